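#' Construct a genome (one agent's evolvable parameters)
#'
#' A genome bundles the evolvable weight sets of one architecture with the
#' per-layer sigmoid bias and gain. Weight matrices are stored
#' post-synaptic-by-pre-synaptic:
#' `ff_w` is 121 x 4 (PPC neuron i to motor neuron m), `fb_w` is 121 x 4
#' (motor to PPC; only for FB/FBLAT), `lat_w` is 121 x 121 (PPC to PPC,
#' self-connections on the diagonal; only for LAT/FBLAT).
#'
#' Legal ranges are hard bounds: weights in \[-1, 1\], biases in \[-5, 5\],
#' gains in \[0.1, 10\].
#'
#' @param arch Architecture name or object.
#' @param ff_w 121 x 4 feedforward weight matrix.
#' @param fb_w 121 x 4 feedback weight matrix (required iff the architecture
#'   has feedback; must be `NULL` otherwise).
#' @param lat_w 121 x 121 lateral weight matrix (iff the architecture has
#'   lateral connections).
#' @param ppc_bias,ppc_gain,m1_bias,m1_gain Scalar sigmoid parameters shared
#'   by all neurons of the respective layer.
#' @return An object of class `"pr_genome"`.
#' @seealso [random_genome()], [fixture_genomes()], [genome_to_vector()]
#' @export
new_genome <- function(arch, ff_w, fb_w = NULL, lat_w = NULL,
                       ppc_bias = 0, ppc_gain = 1,
                       m1_bias = 0, m1_gain = 1) {
  arch <- architecture_spec(arch)
  ff_w <- as.matrix(ff_w)
  stopifnot(identical(dim(ff_w), c(N_PPC, N_M1)))
  if (arch$has_feedback) {
    stopifnot(!is.null(fb_w))
    fb_w <- as.matrix(fb_w)
    stopifnot(identical(dim(fb_w), c(N_PPC, N_M1)))
  } else if (!is.null(fb_w)) {
    stop("architecture ", arch$name, " has no feedback weights")
  }
  if (arch$has_lateral) {
    stopifnot(!is.null(lat_w))
    lat_w <- as.matrix(lat_w)
    stopifnot(identical(dim(lat_w), c(N_PPC, N_PPC)))
  } else if (!is.null(lat_w)) {
    stop("architecture ", arch$name, " has no lateral weights")
  }
  g <- structure(
    list(arch = arch, ff_w = ff_w, fb_w = fb_w, lat_w = lat_w,
         ppc_bias = as.numeric(ppc_bias), ppc_gain = as.numeric(ppc_gain),
         m1_bias = as.numeric(m1_bias), m1_gain = as.numeric(m1_gain)),
    class = "pr_genome"
  )
  validate_genome(g)
  g
}

#' Validate genome ranges and shapes
#'
#' @param genome A `"pr_genome"` object.
#' @return The genome, invisibly; errors on violation.
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "pr_genome"))
  w <- c(genome$ff_w, genome$fb_w, genome$lat_w)
  if (any(w < -1 | w > 1)) stop("weights outside [-1, 1]")
  b <- c(genome$ppc_bias, genome$m1_bias)
  if (any(b < -5 | b > 5)) stop("biases outside [-5, 5]")
  k <- c(genome$ppc_gain, genome$m1_gain)
  if (any(k < 0.1 | k > 10)) stop("gains outside [0.1, 10]")
  if (length(w) != genome_weight_count(genome$arch))
    stop("weight count does not match architecture")
  invisible(genome)
}

#' @export
print.pr_genome <- function(x, ...) {
  cat(sprintf("<pr_genome> %s: %d weights + 4 neuron parameters\n",
              x$arch$name, genome_weight_count(x$arch)))
  invisible(x)
}

#' Draw a random genome
#'
#' Weights uniform on \[-1, 1\], biases uniform on \[-5, 5\], gains uniform on
#' \[0.1, 10\], matching the initialization of the evolutionary search.
#' Uses the R random-number stream (seed with [set.seed()]).
#'
#' @param arch Architecture name or object.
#' @return A `"pr_genome"`.
#' @export
random_genome <- function(arch) {
  arch <- architecture_spec(arch)
  ff <- matrix(stats::runif(N_PPC * N_M1, -1, 1), N_PPC, N_M1)
  fb <- if (arch$has_feedback)
    matrix(stats::runif(N_PPC * N_M1, -1, 1), N_PPC, N_M1)
  lat <- if (arch$has_lateral)
    matrix(stats::runif(N_PPC * N_PPC, -1, 1), N_PPC, N_PPC)
  new_genome(arch, ff, fb, lat,
             ppc_bias = stats::runif(1, -5, 5),
             ppc_gain = stats::runif(1, 0.1, 10),
             m1_bias = stats::runif(1, -5, 5),
             m1_gain = stats::runif(1, 0.1, 10))
}

#' Flatten a genome to its parameter vector
#'
#' Fixed documented ordering: feedforward weights by PPC index then motor
#' index (for each PPC neuron i = 1..121, its 4 outgoing motor weights);
#' feedback weights in the same layout (for each PPC neuron, its 4 incoming
#' motor weights); lateral weights presynaptic-major (for each presynaptic
#' PPC neuron, its 121 outgoing weights by postsynaptic index); then
#' `ppc_bias`, `ppc_gain`, `m1_bias`, `m1_gain`.
#'
#' @param genome A `"pr_genome"`.
#' @return Numeric vector of length [genome_param_count()].
#' @export
genome_to_vector <- function(genome) {
  stopifnot(inherits(genome, "pr_genome"))
  c(as.vector(t(genome$ff_w)),
    if (!is.null(genome$fb_w)) as.vector(t(genome$fb_w)),
    if (!is.null(genome$lat_w)) as.vector(genome$lat_w),
    genome$ppc_bias, genome$ppc_gain, genome$m1_bias, genome$m1_gain)
}

#' Rebuild a genome from its parameter vector
#'
#' Inverse of [genome_to_vector()].
#'
#' @param arch Architecture name or object.
#' @param v Numeric vector in the documented flat ordering.
#' @param validate Check range invariants (default `TRUE`).
#' @return A `"pr_genome"`.
#' @export
vector_to_genome <- function(arch, v, validate = TRUE) {
  arch <- architecture_spec(arch)
  if (length(v) != genome_param_count(arch))
    stop("parameter vector has length ", length(v), ", expected ",
         genome_param_count(arch))
  pos <- 0L
  take <- function(n) {
    out <- v[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  ff <- t(matrix(take(N_PPC * N_M1), N_M1, N_PPC))
  fb <- if (arch$has_feedback) t(matrix(take(N_PPC * N_M1), N_M1, N_PPC))
  lat <- if (arch$has_lateral) matrix(take(N_PPC * N_PPC), N_PPC, N_PPC)
  rest <- take(4L)
  g <- structure(
    list(arch = arch, ff_w = ff, fb_w = fb, lat_w = lat,
         ppc_bias = rest[1], ppc_gain = rest[2],
         m1_bias = rest[3], m1_gain = rest[4]),
    class = "pr_genome"
  )
  if (validate) validate_genome(g)
  g
}

#' Read or write a genome as JSON
#'
#' The JSON document carries the architecture tag, a schema version and the
#' flat parameter vector in the [genome_to_vector()] ordering.
#'
#' @param genome A `"pr_genome"`.
#' @param path File path.
#' @return `read_genome` returns a `"pr_genome"`; `write_genome` its path,
#'   invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "pr_genome"))
  obj <- list(schema = "pr_genome/1", arch = genome$arch$name,
              params = genome_to_vector(genome))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "pr_genome/1"))
    stop("unrecognized genome schema: ", obj$schema)
  vector_to_genome(obj$arch, as.numeric(obj$params))
}

#' Deterministic fixture genomes
#'
#' Named genomes used across examples and tests: `zero` (all weights 0,
#' biases 0, gains 1 -- an agent that never moves), `bounds` (every parameter
#' at a legal extreme), and `seeded_random(s)` via the `seed` argument
#' (reproducible uniform draws).
#'
#' @param arch Architecture name or object.
#' @param seed Integer seed for the `random` member.
#' @return Named list with elements `zero`, `bounds`, `random`.
#' @export
fixture_genomes <- function(arch, seed = 1L) {
  arch <- architecture_spec(arch)
  zero <- new_genome(
    arch, matrix(0, N_PPC, N_M1),
    fb_w = if (arch$has_feedback) matrix(0, N_PPC, N_M1),
    lat_w = if (arch$has_lateral) matrix(0, N_PPC, N_PPC),
    ppc_bias = 0, ppc_gain = 1, m1_bias = 0, m1_gain = 1
  )
  bounds <- new_genome(
    arch, matrix(1, N_PPC, N_M1),
    fb_w = if (arch$has_feedback) matrix(-1, N_PPC, N_M1),
    lat_w = if (arch$has_lateral) matrix(-1, N_PPC, N_PPC),
    ppc_bias = -5, ppc_gain = 0.1, m1_bias = 5, m1_gain = 10
  )
  rnd <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    random_genome(arch)
  })
  list(zero = zero, bounds = bounds, random = rnd)
}
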