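#' The eight center-out targets
#'
#' Four cardinal targets at 25 degrees eccentricity and four diagonal targets
#' at (+/-25, +/-25) (Euclidean eccentricity 25*sqrt(2), reported as 35
#' degrees). Trials are ordered counter-clockwise by direction angle starting
#' at rightward (0 degrees): trial k points at angle (k - 1) * 45 degrees.
#'
#' @return A data frame with columns `trial`, `x`, `y`, `angle` (radians).
#' @export
make_targets <- function() {
  ang <- (0:7) * pi / 4
  r <- ifelse(0:7 %% 2 == 0, 25, 25 * sqrt(2))
  data.frame(trial = 1:8,
             x = round(r * cos(ang), 12),
             y = round(r * sin(ang), 12),
             angle = ang)
}

#' Task mode: visually or memory guided
#'
#' In the VG task the target is illuminated for all 50 timesteps; in the MG
#' task it extinguishes after 5 timesteps (visible on world timesteps 1..5),
#' so an accurate reach requires an internally maintained motor plan. Hand
#' vision persists in both modes.
#'
#' @param name `"VG"` or `"MG"`.
#' @param visible_timesteps Override for the visibility window (defaults 50
#'   for VG, 5 for MG).
#' @return Object of class `"pr_task_mode"`.
#' @export
task_mode <- function(name = c("VG", "MG"), visible_timesteps = NULL) {
  name <- match.arg(toupper(name), c("VG", "MG"))
  if (is.null(visible_timesteps))
    visible_timesteps <- if (name == "VG") 50L else 5L
  structure(list(name = name,
                 visible_timesteps = as.integer(visible_timesteps)),
            class = "pr_task_mode")
}

#' Population-vector decode of the motor layer
#'
#' The four motor neurons encode Up, Down, Left, Right (preferred directions
#' pi/2, 3*pi/2, pi, 0). The decoded displacement per timestep is the
#' rate-weighted vector sum scaled by `v`:
#' `dx = v * (s_Right - s_Left)`, `dy = v * (s_Up - s_Down)`.
#' With `v = 2` the cardinal speed cap is 2 deg/timestep (200 deg/s) and the
#' diagonal cap 2*sqrt(2) (about 2.83 deg/timestep).
#'
#' @param m1_rates Length-4 rates ordered (Up, Down, Left, Right).
#' @param v Scale constant (default 2).
#' @return Length-2 numeric `c(dx, dy)` in degrees/timestep.
#' @examples
#' decode_population_vector(c(0, 0, 0, 1))  # (2, 0): cardinal cap
#' decode_population_vector(c(1, 0, 0, 1))  # (2, 2): diagonal, speed 2.83
#' @export
decode_population_vector <- function(m1_rates, v = 2) {
  stopifnot(length(m1_rates) == 4)
  c(v * (m1_rates[4] - m1_rates[3]), v * (m1_rates[1] - m1_rates[2]))
}

#' Simulation settings for a trial
#'
#' Collects the fixed task constants: trial length, sensory delays, decoder
#' scale, sensory projection configuration and the position-encoding rule.
#'
#' @param n_timesteps Trial length (50 timesteps of 10 ms).
#' @param d_vis,d_prop Visual and proprioceptive delays, in timesteps; a
#'   "D-timestep delay" means first arrival ON timestep D.
#' @param v Decoder scale constant.
#' @param sensory A [sensory_projection_config()].
#' @param encoding `"bilinear"` or `"nearest"` sensory placement.
#' @return Object of class `"pr_sim_config"`, with the two projection maps
#'   precomputed.
#' @export
sim_config <- function(n_timesteps = 50L, d_vis = 9L, d_prop = 3L, v = 2,
                       sensory = sensory_projection_config(),
                       encoding = c("bilinear", "nearest")) {
  encoding <- match.arg(encoding)
  stopifnot(n_timesteps >= 1, d_vis >= 1, d_prop >= 1)
  structure(
    list(n_timesteps = as.integer(n_timesteps),
         d_vis = as.integer(d_vis), d_prop = as.integer(d_prop),
         v = v, sensory = sensory, encoding = encoding,
         w_vis = build_sensory_projection(sensory, "vision"),
         w_prop = build_sensory_projection(sensory, "proprioception")),
    class = "pr_sim_config"
  )
}

#' Run one reaching trial
#'
#' Executes the full sensorimotor loop for one target: at each timestep the
#' world (hand position, target visibility) is recorded into the sensory
#' history, the delayed drive is computed, the network takes one synchronous
#' step, the motor rates are decoded into a hand displacement, and the hand
#' (clamped to the +/-50 degree space) and hand-target distance are recorded.
#' Distances are recorded after the movement of each timestep. The hand
#' starts at (0, 0) with gaze fixed at the center.
#'
#' @param genome A `"pr_genome"`.
#' @param target Either a row of [make_targets()], a length-2 numeric
#'   position, or a trial index 1..8.
#' @param mode A [task_mode()] or mode name.
#' @param config A [sim_config()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference engine
#'   composed from the exported primitives); the two are exactly equivalent.
#' @return Object of class `"pr_trial_record"`: matrices `hand` (50 x 2),
#'   `ppc` (50 x 121), `m1` (50 x 4), vector `distance` (50), plus `target`
#'   and `mode`.
#' @export
run_trial <- function(genome, target, mode = "VG", config = sim_config(),
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(genome, "pr_genome"), inherits(config, "pr_sim_config"))
  mode <- if (inherits(mode, "pr_task_mode")) mode else task_mode(mode)
  tgt <- resolve_target(target)
  rec <- if (engine == "cpp") {
    run_trial_engine_cpp(genome, tgt, mode, config, record = TRUE)
  } else {
    run_trial_engine_r(genome, tgt, mode, config)
  }
  structure(c(rec, list(target = tgt, mode = mode)),
            class = "pr_trial_record")
}

resolve_target <- function(target) {
  if (is.data.frame(target)) return(c(x = target$x[1], y = target$y[1]))
  if (is.numeric(target) && length(target) == 1) {
    tg <- make_targets()
    return(c(x = tg$x[target], y = tg$y[target]))
  }
  stopifnot(is.numeric(target), length(target) == 2)
  c(x = target[1], y = target[2])
}

empty_mat <- matrix(numeric(0), 0, 0)

run_trial_engine_cpp <- function(genome, tgt, mode, config, record = TRUE) {
  cpp_run_trial(
    genome$arch$has_feedback, genome$arch$has_lateral,
    genome$ff_w,
    if (is.null(genome$fb_w)) empty_mat else genome$fb_w,
    if (is.null(genome$lat_w)) empty_mat else genome$lat_w,
    genome$ppc_bias, genome$ppc_gain, genome$m1_bias, genome$m1_gain,
    config$w_vis, config$w_prop,
    tgt[1], tgt[2], mode$visible_timesteps,
    config$n_timesteps, config$d_vis, config$d_prop,
    config$v, config$encoding == "nearest", record
  )
}

# Reference engine: the same loop written from the exported primitives.
run_trial_engine_r <- function(genome, tgt, mode, config) {
  n <- config$n_timesteps
  state <- init_state(genome)
  hand <- c(0, 0)
  history <- list(vision = vector("list", n), prop = vector("list", n))
  hand_out <- matrix(NA_real_, n, 2)
  ppc_out <- matrix(NA_real_, n, N_PPC)
  m1_out <- matrix(NA_real_, n, N_M1)
  dist <- numeric(n)
  for (t in seq_len(n)) {
    history$vision[[t]] <- encode_vision(hand, tgt,
                                         t <= mode$visible_timesteps,
                                         config$encoding)
    history$prop[[t]] <- encode_proprioception(hand, config$encoding)
    drive <- delayed_drive(history, t, config$w_vis, config$w_prop,
                           config$d_vis, config$d_prop)
    state <- step(state, genome, drive)
    delta <- decode_population_vector(state$m1_rates, config$v)
    hand <- pmin(pmax(hand + delta, -50), 50)
    hand_out[t, ] <- hand
    ppc_out[t, ] <- state$ppc_rates
    m1_out[t, ] <- state$m1_rates
    dist[t] <- sqrt(sum((hand - tgt)^2))
  }
  list(hand = hand_out, ppc = ppc_out, m1 = m1_out, distance = dist)
}

#' @export
print.pr_trial_record <- function(x, ...) {
  cat(sprintf(
    "<pr_trial_record> %s trial to (%g, %g): final distance %.3f deg\n",
    x$mode$name, x$target[1], x$target[2],
    x$distance[length(x$distance)]))
  invisible(x)
}

#' Evaluate an agent's fitness over the eight trials
#'
#' Fitness is the hand-target Euclidean distance summed over every timestep
#' and trial (minimized). The corrected fitness subtracts the analytic
#' optimum from [optimal_fitness_bound()], so a perfect agent scores 0.
#' Deterministic: a trial has no stochastic elements.
#'
#' @param genome A `"pr_genome"`.
#' @param mode Task mode (`"VG"` by default; training uses VG).
#' @param config A [sim_config()].
#' @param engine `"cpp"` or `"r"`.
#' @return Object of class `"pr_fitness"`: `raw`, `corrected`, and
#'   `per_trial` (length 8).
#' @export
evaluate_agent <- function(genome, mode = "VG", config = sim_config(),
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  mode <- if (inherits(mode, "pr_task_mode")) mode else task_mode(mode)
  tg <- make_targets()
  per_trial <- if (engine == "cpp") {
    as.numeric(cpp_eval_params(
      genome_to_vector(genome),
      genome$arch$has_feedback, genome$arch$has_lateral,
      config$w_vis, config$w_prop,
      cbind(tg$x, tg$y), mode$visible_timesteps,
      config$n_timesteps, config$d_vis, config$d_prop,
      config$v, config$encoding == "nearest"
    ))
  } else {
    vapply(1:8, function(n) {
      sum(run_trial(genome, tg[n, ], mode, config, engine = "r")$distance)
    }, numeric(1))
  }
  raw <- sum(per_trial)
  structure(
    list(raw = raw,
         corrected = raw - optimal_fitness_bound(config = config),
         per_trial = per_trial, mode = mode$name),
    class = "pr_fitness"
  )
}

#' @export
print.pr_fitness <- function(x, ...) {
  cat(sprintf("<pr_fitness> %s: raw %.2f, corrected %.2f\n",
              x$mode, x$raw, x$corrected))
  invisible(x)
}

#' Distance-minimizing trajectory for one target
#'
#' The optimal agent stays put while no delayed visual information can have
#' influenced motor output (vision reaches the PPC at timestep 9, and the
#' PPC-to-motor lag adds one timestep, so the first informed movement is at
#' timestep 10), then moves straight at the per-axis speed cap and stops
#' exactly on the target.
#'
#' @param target Target as in [run_trial()].
#' @param n_timesteps Trial length.
#' @param first_move First timestep at which movement can reflect the target.
#' @param v_max Per-axis speed cap in deg/timestep.
#' @return Matrix `n_timesteps` x 2 of post-movement hand positions.
#' @export
optimal_trajectory <- function(target, n_timesteps = 50L, first_move = 10L,
                               v_max = 2) {
  tgt <- resolve_target(target)
  hand <- c(0, 0)
  out <- matrix(NA_real_, n_timesteps, 2)
  for (t in seq_len(n_timesteps)) {
    if (t >= first_move) {
      rem <- tgt - hand
      hand <- hand + sign(rem) * pmin(abs(rem), v_max)
    }
    out[t, ] <- hand
  }
  out
}

#' Analytic optimal (minimum) fitness
#'
#' Sums the hand-target distance of the distance-minimizing trajectory of
#' [optimal_trajectory()] over all timesteps and trials; under the standard
#' task this evaluates to 3563.4 (printed at one decimal). Subtracted from
#' raw fitness to normalize the optimum to 0.
#'
#' @param targets Data frame of targets (default [make_targets()]).
#' @param n_timesteps,first_move,v_max See [optimal_trajectory()].
#' @param config Optional [sim_config()]; supplies `n_timesteps` and the
#'   first-move timestep (`d_vis + 1`) and cap (`v`) consistently.
#' @return Summed degrees of visual angle (numeric scalar).
#' @export
optimal_fitness_bound <- function(targets = make_targets(),
                                  n_timesteps = 50L, first_move = 10L,
                                  v_max = 2, config = NULL) {
  if (!is.null(config)) {
    n_timesteps <- config$n_timesteps
    first_move <- config$d_vis + 1L
    v_max <- config$v
  }
  total <- 0
  for (n in seq_len(nrow(targets))) {
    traj <- optimal_trajectory(targets[n, ], n_timesteps, first_move, v_max)
    total <- total +
      sum(sqrt((traj[, 1] - targets$x[n])^2 + (traj[, 2] - targets$y[n])^2))
  }
  total
}
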