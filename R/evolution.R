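#' Evolution-strategy configuration
#'
#' (mu, lambda) evolution strategy with elitism, roulette-wheel parent
#' selection, uniform crossover and Gaussian mutation. Defaults follow the
#' study conditions: 20 agents per generation, agent-level mutation
#' probability 0.4, per-parameter perturbation probability 0.5, Gaussian
#' sigmas 0.3 (weights), 3 (biases) and 1.5 (gains). The full-scale search
#' ran 25000 generations; the `generations` default here is the desk scale
#' used throughout the package's own experiments.
#'
#' @param population_size Agents per generation (default 20).
#' @param generations Number of generations.
#' @param p_mutate_agent Probability an offspring receives mutation (0.4).
#' @param p_mutate_param Per-parameter perturbation probability given the
#'   agent mutates (0.5).
#' @param sigma_weights,sigma_bias,sigma_gain Gaussian mutation SDs per
#'   parameter class.
#' @param elite_count Best agents copied unchanged each generation (>= 1).
#' @param crossover `"uniform"` (default) or `"one_point"`.
#' @param seed Integer RNG seed for the run.
#' @return Object of class `"pr_ea_config"`.
#' @export
ea_config <- function(population_size = 20L, generations = 1500L,
                      p_mutate_agent = 0.4, p_mutate_param = 0.5,
                      sigma_weights = 0.3, sigma_bias = 3, sigma_gain = 1.5,
                      elite_count = 1L, crossover = c("uniform", "one_point"),
                      seed = 1L) {
  crossover <- match.arg(crossover)
  stopifnot(p_mutate_agent >= 0, p_mutate_agent <= 1,
            p_mutate_param >= 0, p_mutate_param <= 1,
            sigma_weights > 0, sigma_bias > 0, sigma_gain > 0,
            elite_count >= 1, population_size >= elite_count + 2,
            generations >= 0)
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         p_mutate_agent = p_mutate_agent, p_mutate_param = p_mutate_param,
         sigma_weights = sigma_weights, sigma_bias = sigma_bias,
         sigma_gain = sigma_gain, elite_count = as.integer(elite_count),
         crossover = crossover, seed = as.integer(seed)),
    class = "pr_ea_config"
  )
}

# Per-parameter mutation SD in flat-vector order: weights, then
# (ppc_bias, ppc_gain, m1_bias, m1_gain).
param_sigmas <- function(arch, cfg) {
  nw <- genome_weight_count(arch)
  c(rep(cfg$sigma_weights, nw),
    cfg$sigma_bias, cfg$sigma_gain, cfg$sigma_bias, cfg$sigma_gain)
}

param_bounds <- function(arch) {
  nw <- genome_weight_count(arch)
  list(lo = c(rep(-1, nw), -5, 0.1, -5, 0.1),
       hi = c(rep(1, nw), 5, 10, 5, 10))
}

# Flat-vector mutation kernel shared by mutate() and the evolve() loop.
mutate_vec <- function(v, arch, cfg) {
  hit <- stats::runif(length(v)) < cfg$p_mutate_param
  if (any(hit)) {
    sig <- param_sigmas(arch, cfg)
    v[hit] <- v[hit] + stats::rnorm(sum(hit), 0, sig[hit])
    b <- param_bounds(arch)
    v <- pmin(pmax(v, b$lo), b$hi)
  }
  v
}

#' Gaussian mutation of a genome
#'
#' Each free parameter is independently perturbed with probability
#' `p_mutate_param` by zero-mean Gaussian noise with the class-specific SD
#' (weights 0.3, biases 3, gains 1.5 by default); results are clamped to the
#' legal ranges, which are hard bounds. The caller is responsible for the
#' agent-level mutation draw (`p_mutate_agent`).
#'
#' @param genome A `"pr_genome"`.
#' @param cfg An [ea_config()].
#' @return The mutated `"pr_genome"`.
#' @export
mutate <- function(genome, cfg = ea_config()) {
  v <- mutate_vec(genome_to_vector(genome), genome$arch, cfg)
  vector_to_genome(genome$arch, v, validate = FALSE)
}

# Roulette selection weights under minimization: weight proportional to
# (worst - fitness + eps), eps = 1e-6 * fitness range; degenerate
# all-equal populations fall back to uniform.
roulette_weights <- function(fitnesses) {
  rng <- max(fitnesses) - min(fitnesses)
  if (rng == 0) return(rep(1, length(fitnesses)))
  max(fitnesses) - fitnesses + 1e-6 * rng
}

#' Roulette-selected crossover
#'
#' Two parents are drawn (independently, with replacement) with probability
#' proportional to a fitness-derived selection weight
#' (`worst - fitness + eps`, minimization). The offspring takes each free
#' parameter from either parent with probability 0.5 (uniform crossover), or
#' the prefix/suffix split of a random cut point (`one_point`).
#'
#' @param population List of `"pr_genome"` (length >= 2).
#' @param fitnesses Numeric fitness per parent (finite; lower is better).
#' @param cfg An [ea_config()].
#' @return Offspring `"pr_genome"`.
#' @export
crossover_roulette <- function(population, fitnesses, cfg = ea_config()) {
  if (length(population) < 2) stop("need at least 2 parents")
  stopifnot(length(fitnesses) == length(population), all(is.finite(fitnesses)))
  vecs <- lapply(population, genome_to_vector)
  v <- crossover_vec(vecs, fitnesses, cfg)
  vector_to_genome(population[[1]]$arch, v, validate = FALSE)
}

# Flat-vector crossover kernel shared by crossover_roulette() and evolve().
crossover_vec <- function(vecs, fitnesses, cfg) {
  w <- roulette_weights(fitnesses)
  idx <- sample.int(length(vecs), 2, replace = TRUE, prob = w)
  a <- vecs[[idx[1]]]
  b <- vecs[[idx[2]]]
  if (cfg$crossover == "uniform") {
    v <- b
    pick <- stats::runif(length(a)) < 0.5
    v[pick] <- a[pick]
    v
  } else {
    cut <- sample.int(length(a) - 1L, 1L)
    c(a[seq_len(cut)], b[(cut + 1L):length(a)])
  }
}

#' Evolve one population on the reaching task
#'
#' Generation loop: evaluate all agents (raw fitness, deterministic); carry
#' the `elite_count` best unchanged; fill the remainder with
#' roulette-crossover offspring, each mutated with probability
#' `p_mutate_agent`; record the best corrected fitness. Fully reproducible
#' from `cfg$seed`.
#'
#' @param arch Architecture name or object.
#' @param cfg An [ea_config()].
#' @param mode Task mode for fitness evaluation (training task is `"VG"`).
#' @param config A [sim_config()].
#' @param verbose Print a progress line every `log_every` generations
#'   (0 = silent).
#' @param log_every Logging interval in generations.
#' @return Object of class `"pr_run_result"`: `best_genome`, `best_fitness`
#'   (corrected), `trace` (best-so-far corrected fitness per generation,
#'   non-increasing), `seed`, `evaluations`.
#' @export
evolve <- function(arch, cfg = ea_config(), mode = "VG",
                   config = sim_config(), verbose = FALSE, log_every = 100L) {
  arch <- architecture_spec(arch)
  mode <- if (inherits(mode, "pr_task_mode")) mode else task_mode(mode)
  set.seed(cfg$seed)
  bound <- optimal_fitness_bound(config = config)
  tg <- make_targets()
  tmat <- cbind(tg$x, tg$y)
  raw_fitness <- function(v) {
    sum(cpp_eval_params(
      v, arch$has_feedback, arch$has_lateral,
      config$w_vis, config$w_prop, tmat, mode$visible_timesteps,
      config$n_timesteps, config$d_vis, config$d_prop,
      config$v, config$encoding == "nearest"))
  }

  # population held as flat parameter vectors (genome serialization order)
  pop <- replicate(cfg$population_size,
                   genome_to_vector(random_genome(arch)), simplify = FALSE)
  fit <- vapply(pop, raw_fitness, numeric(1))
  evals <- cfg$population_size
  trace <- numeric(cfg$generations)
  best_i <- which.min(fit)
  best_vec <- pop[[best_i]]
  best_fit <- fit[best_i]

  gen <- 0L
  while (gen < cfg$generations) {
    gen <- gen + 1L
    ord <- order(fit)
    elite_idx <- ord[seq_len(cfg$elite_count)]
    n_off <- cfg$population_size - cfg$elite_count
    offspring <- vector("list", n_off)
    for (i in seq_len(n_off)) {
      child <- crossover_vec(pop, fit, cfg)
      if (stats::runif(1) < cfg$p_mutate_agent)
        child <- mutate_vec(child, arch, cfg)
      offspring[[i]] <- child
    }
    off_fit <- vapply(offspring, raw_fitness, numeric(1))
    evals <- evals + n_off
    pop <- c(pop[elite_idx], offspring)
    fit <- c(fit[elite_idx], off_fit)
    gi <- which.min(fit)
    if (fit[gi] < best_fit) {
      best_fit <- fit[gi]
      best_vec <- pop[[gi]]
    }
    trace[gen] <- best_fit - bound
    if (verbose && (gen %% log_every == 0L || gen == cfg$generations))
      message(sprintf("gen %d: best corrected %.2f, mean %.2f",
                      gen, best_fit - bound, mean(fit) - bound))
  }
  structure(
    list(arch = arch$name,
         best_genome = vector_to_genome(arch, best_vec, validate = FALSE),
         best_fitness = best_fit - bound, trace = trace,
         seed = cfg$seed, evaluations = evals),
    class = "pr_run_result"
  )
}

#' @export
print.pr_run_result <- function(x, ...) {
  cat(sprintf(
    "<pr_run_result> %s seed %d: best corrected fitness %.2f after %d evaluations\n",
    x$arch, x$seed, x$best_fitness, x$evaluations))
  invisible(x)
}

#' Independent evolution runs and champion selection
#'
#' Runs [evolve()] once per seed (runs are independent and self-contained);
#' the champion is the best agent with the minimum fitness across runs.
#'
#' @param arch Architecture name or object.
#' @param cfg An [ea_config()]; its `seed` field is replaced per run.
#' @param seeds Integer vector of distinct seeds (one run each).
#' @param ... Passed to [evolve()].
#' @return Object of class `"pr_population_result"`: `runs` (list of
#'   `"pr_run_result"`), `champion` (index), `champion_genome`.
#' @export
run_population <- function(arch, cfg = ea_config(), seeds = 1:5, ...) {
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  runs <- lapply(seeds, function(s) {
    cfg$seed <- as.integer(s)
    evolve(arch, cfg, ...)
  })
  best <- vapply(runs, function(r) r$best_fitness, numeric(1))
  ch <- which.min(best)
  structure(
    list(arch = architecture_spec(arch)$name, runs = runs,
         champion = ch, champion_genome = runs[[ch]]$best_genome),
    class = "pr_population_result"
  )
}

#' @export
print.pr_population_result <- function(x, ...) {
  best <- vapply(x$runs, function(r) r$best_fitness, numeric(1))
  cat(sprintf(
    "<pr_population_result> %s: %d runs, champion (run %d) corrected fitness %.2f\n",
    x$arch, length(x$runs), x$champion, min(best)))
  invisible(x)
}
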