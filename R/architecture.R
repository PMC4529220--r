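#' Network architecture specification
#'
#' The four model variants differ only in their projections onto the PPC
#' layer: all have fixed sensory projections and evolvable feedforward
#' PPC-to-motor weights; `FB` adds an efference copy (motor-to-PPC feedback),
#' `LAT` adds full recurrent PPC-to-PPC connectivity (self-connections
#' included), and `FBLAT` has both.
#'
#' @param name One of `"FF"`, `"FB"`, `"LAT"`, `"FBLAT"` (case-insensitive).
#' @return An object of class `"pr_architecture"` with elements `name`,
#'   `has_feedback` and `has_lateral`.
#' @examples
#' architecture_spec("LAT")$has_lateral
#' @export
architecture_spec <- function(name) {
  if (inherits(name, "pr_architecture")) return(name)
  name <- toupper(match.arg(tolower(name), c("ff", "fb", "lat", "fblat")))
  structure(
    list(name = name,
         has_feedback = name %in% c("FB", "FBLAT"),
         has_lateral = name %in% c("LAT", "FBLAT")),
    class = "pr_architecture"
  )
}

#' @export
print.pr_architecture <- function(x, ...) {
  cat(sprintf("<pr_architecture> %s (feedback: %s, lateral: %s)\n",
              x$name, x$has_feedback, x$has_lateral))
  invisible(x)
}

# Layer sizes are fixed across all architectures.
PPC_GRID <- 11L
N_PPC <- PPC_GRID * PPC_GRID
N_M1 <- 4L

#' Number of evolvable weights for an architecture
#'
#' Closed forms: FF = 121*4 = 484; FB = 968; LAT = 484 + 121^2 = 15125;
#' FBLAT = 15609. Bias/gain parameters (4 in total) are counted separately
#' by [genome_param_count()].
#'
#' @param arch Architecture name or `"pr_architecture"` object.
#' @return Integer weight count.
#' @export
genome_weight_count <- function(arch) {
  arch <- architecture_spec(arch)
  n <- N_PPC * N_M1
  if (arch$has_feedback) n <- n + N_PPC * N_M1
  if (arch$has_lateral) n <- n + N_PPC * N_PPC
  as.integer(n)
}

#' @rdname genome_weight_count
#' @export
genome_param_count <- function(arch) genome_weight_count(arch) + 4L

# Row/column (1-based) of each PPC/sensory neuron, column-major flattening:
# neuron n sits at grid[r, c] with r = ((n-1) %% 11) + 1, c = ((n-1) %/% 11) + 1.
grid_rc <- function() {
  n <- seq_len(N_PPC) - 1L
  cbind(r = n %% PPC_GRID + 1L, c = n %/% PPC_GRID + 1L)
}

# Degrees of visual angle of each grid node: x = (c-6)*10, y = (6-r)*10.
grid_xy <- function() {
  rc <- grid_rc()
  cbind(x = (rc[, "c"] - 6) * 10, y = (6 - rc[, "r"]) * 10)
}

# 121x121 Euclidean distances between grid indices (index units).
grid_index_distance <- function() {
  rc <- grid_rc()
  dr <- outer(rc[, "r"], rc[, "r"], "-")
  dc <- outer(rc[, "c"], rc[, "c"], "-")
  sqrt(dr^2 + dc^2)
}
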