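#' Scale presets for experiments
#'
#' `paper` encodes the full study conditions (25000 generations, 100
#' independent runs, 20 agents per generation); `desk` is the scaled-down
#' battery used by the package's own reproductions (1500 generations, 5
#' runs); `test` is a smoke scale (50 generations, 2 runs).
#'
#' @param preset `"paper"`, `"desk"` or `"test"`.
#' @return List with `generations`, `n_runs`, `population_size`.
#' @export
scale_preset <- function(preset = c("desk", "paper", "test")) {
  preset <- match.arg(preset)
  switch(preset,
         paper = list(generations = 25000L, n_runs = 100L, population_size = 20L),
         desk = list(generations = 1500L, n_runs = 5L, population_size = 20L),
         test = list(generations = 50L, n_runs = 2L, population_size = 20L))
}

config_defaults <- function() {
  list(
    preset = "desk",
    architectures = c("FF", "FB", "LAT", "FBLAT"),
    task = list(mode = "VG", visible_timesteps = NULL),
    delays = list(vision = 9L, proprioception = 3L),
    sensory = list(f_vision = 2, f_prop = -4, g = 200, divisor = 20),
    decode = list(v = 2),
    encoding = "bilinear",
    ea = list(population_size = NULL, generations = NULL,
              p_mutate_agent = 0.4, p_mutate_param = 0.5,
              sigma_weights = 0.3, sigma_bias = 3, sigma_gain = 1.5,
              elite_count = 1L, crossover = "uniform"),
    seed = 1L,
    out_dir = "parietoreach-results"
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop("unknown configuration key: ", paste0(path, k))
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]]))
        stop("configuration key ", paste0(path, k), " must be a mapping")
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(path, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load, validate or save an experiment configuration
#'
#' Configurations are YAML mappings; unknown keys are rejected and defaults
#' (the `desk` preset) fill in anything omitted. An empty file yields the
#' full default configuration.
#'
#' @param path YAML file path.
#' @return `load_config` returns a validated `"pr_experiment_config"`;
#'   `save_config` writes one and returns the path invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(merge_config(config_defaults(), user))
}

#' @rdname load_config
#' @param cfg A configuration list.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

validate_config <- function(cfg) {
  scale <- scale_preset(cfg$preset)
  if (is.null(cfg$ea$generations)) cfg$ea$generations <- scale$generations
  if (is.null(cfg$ea$population_size))
    cfg$ea$population_size <- scale$population_size
  if (cfg$ea$generations < 0) stop("ea.generations must be >= 0")
  if (cfg$ea$population_size < cfg$ea$elite_count + 2)
    stop("ea.population_size must be at least elite_count + 2")
  cfg$architectures <- vapply(cfg$architectures,
                              function(a) architecture_spec(a)$name,
                              character(1), USE.NAMES = FALSE)
  if (cfg$delays$vision < 1 || cfg$delays$proprioception < 1)
    stop("delays must be >= 1 timestep")
  if (!cfg$encoding %in% c("bilinear", "nearest"))
    stop("encoding must be 'bilinear' or 'nearest'")
  structure(cfg, class = "pr_experiment_config")
}

config_to_sim <- function(cfg) {
  sim_config(
    d_vis = cfg$delays$vision, d_prop = cfg$delays$proprioception,
    v = cfg$decode$v,
    sensory = sensory_projection_config(
      f_vision = cfg$sensory$f_vision, f_prop = cfg$sensory$f_prop,
      g = cfg$sensory$g, divisor = cfg$sensory$divisor),
    encoding = cfg$encoding
  )
}

config_to_ea <- function(cfg, n_runs = NULL) {
  ea_config(
    population_size = cfg$ea$population_size,
    generations = cfg$ea$generations,
    p_mutate_agent = cfg$ea$p_mutate_agent,
    p_mutate_param = cfg$ea$p_mutate_param,
    sigma_weights = cfg$ea$sigma_weights,
    sigma_bias = cfg$ea$sigma_bias, sigma_gain = cfg$ea$sigma_gain,
    elite_count = cfg$ea$elite_count, crossover = cfg$ea$crossover,
    seed = cfg$seed
  )
}

#' Write a trial record to CSV
#'
#' One row per timestep with columns (trial, timestep, hand_x, hand_y,
#' distance, m1_up, m1_down, m1_left, m1_right); the PPC rates go to a
#' companion file with columns (trial, timestep, ppc_001..ppc_121).
#'
#' A JSON sidecar (suffix `.json`) records the task mode and target of each
#' trial.
#'
#' @param records List of `"pr_trial_record"` (one per trial).
#' @param path Output CSV path; the PPC companion gets suffix `_ppc.csv`.
#' @return Invisibly, the main path.
#' @export
write_trial_records <- function(records, path) {
  main <- do.call(rbind, lapply(seq_along(records), function(n) {
    r <- records[[n]]
    data.frame(trial = n, timestep = seq_len(nrow(r$hand)),
               hand_x = r$hand[, 1], hand_y = r$hand[, 2],
               distance = r$distance,
               m1_up = r$m1[, 1], m1_down = r$m1[, 2],
               m1_left = r$m1[, 3], m1_right = r$m1[, 4])
  }))
  utils::write.csv(main, path, row.names = FALSE)
  ppc <- do.call(rbind, lapply(seq_along(records), function(n) {
    r <- records[[n]]
    d <- as.data.frame(r$ppc)
    names(d) <- sprintf("ppc_%03d", seq_len(N_PPC))
    cbind(data.frame(trial = n, timestep = seq_len(nrow(r$ppc))), d)
  }))
  utils::write.csv(ppc, sub("\\.csv$", "_ppc.csv", path), row.names = FALSE)
  meta <- lapply(seq_along(records), function(n) {
    r <- records[[n]]
    list(trial = n,
         target = list(x = unname(r$target[1]), y = unname(r$target[2])),
         mode = r$mode$name,
         visible_timesteps = r$mode$visible_timesteps,
         timesteps = nrow(r$hand))
  })
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run trials for all eight targets
#'
#' @param genome A `"pr_genome"`.
#' @param mode Task mode.
#' @param config A [sim_config()].
#' @return List of 8 `"pr_trial_record"` in [make_targets()] order.
#' @export
run_all_trials <- function(genome, mode = "VG", config = sim_config()) {
  tg <- make_targets()
  lapply(1:8, function(n) run_trial(genome, tg[n, ], mode, config))
}

#' Run a full experiment and persist its artifacts
#'
#' For each requested architecture: evolve on the VG task over the
#' configured number of independent runs, evaluate every run's best agent
#' and the champion on both VG and MG, write per-run fitness traces and
#' genomes, champion trial records, and a tidy summary CSV (one row per
#' measure, architecture and task). Fully deterministic given the config.
#'
#' @param cfg A `"pr_experiment_config"` (see [load_config()]), or a preset
#'   name.
#' @param verbose Print progress.
#' @return Invisibly, the output directory (the result store).
#' @export
run_experiment <- function(cfg = "desk", verbose = TRUE) {
  if (is.character(cfg))
    cfg <- validate_config(merge_config(config_defaults(),
                                        list(preset = cfg)))
  stopifnot(inherits(cfg, "pr_experiment_config"))
  scale <- scale_preset(cfg$preset)
  sim <- config_to_sim(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  save_config(cfg, file.path(cfg$out_dir, "config.yaml"))

  summary_rows <- list()
  for (ai in seq_along(cfg$architectures)) {
    arch <- cfg$architectures[[ai]]
    seeds <- cfg$seed + 100L * ai + seq_len(scale$n_runs) - 1L
    ea <- config_to_ea(cfg)
    if (verbose) message("evolving ", arch, " (", scale$n_runs, " runs x ",
                         ea$generations, " generations)")
    pop <- run_population(arch, ea, seeds = seeds, config = sim)
    adir <- file.path(cfg$out_dir, arch)
    dir.create(adir, showWarnings = FALSE)
    for (ri in seq_along(pop$runs)) {
      r <- pop$runs[[ri]]
      utils::write.csv(
        data.frame(generation = seq_along(r$trace), best_corrected = r$trace),
        file.path(adir, sprintf("trace_seed%d.csv", r$seed)),
        row.names = FALSE)
      write_genome(r$best_genome,
                   file.path(adir, sprintf("best_seed%d.json", r$seed)))
    }
    champ <- pop$champion_genome
    for (mname in c("VG", "MG")) {
      recs <- run_all_trials(champ, mname, sim)
      write_trial_records(recs,
                          file.path(adir, sprintf("champion_%s.csv", mname)))
      fit <- evaluate_agent(champ, mname, sim)
      te <- target_error(recs)
      vp <- velocity_profile(recs)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        arch = arch, task = mname,
        measure = c("champion_corrected_fitness", "champion_target_error",
                    "champion_peak_velocity", "champion_velocity_peaks"),
        value = c(fit$corrected, te$mean, max(vp$mean),
                  count_velocity_peaks(vp)))
    }
    ffs <- lapply(pop$runs, function(r) r$best_genome$ff_w)
    for (ax in c("vertical", "horizontal")) {
      s <- ipsi_contra_summary(ffs, ax)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        arch = arch, task = "VG",
        measure = paste0("ff_", ax, c("_ipsi_mean", "_contra_mean")),
        value = c(s$ipsi_mean, s$contra_mean))
    }
    if (architecture_spec(arch)$has_lateral) {
      s <- lateral_range_summary(lapply(pop$runs,
                                        function(r) r$best_genome$lat_w))
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        arch = arch, task = "VG",
        measure = paste0("lat_", names(s$mean), "_mean"),
        value = as.numeric(s$mean))
    }
  }
  summary <- do.call(rbind, summary_rows)
  utils::write.csv(summary, file.path(cfg$out_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(cfg$out_dir)
}
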