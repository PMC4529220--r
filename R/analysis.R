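#' Average velocity profile over trials
#'
#' Instantaneous hand speed is the Euclidean displacement between consecutive
#' timesteps, converted to degrees/second (x 100, one timestep being 10 ms).
#' The speed at timestep 1 uses the displacement from the fixed start
#' position (0, 0). Returns the per-timestep mean and SD across trials.
#'
#' @param records List of `"pr_trial_record"` (typically the 8 trials).
#' @return Object of class `"pr_velocity_profile"`: vectors `mean` and `sd`
#'   (length 50), in deg/s.
#' @export
velocity_profile <- function(records) {
  stopifnot(length(records) >= 1)
  n <- nrow(records[[1]]$hand)
  speeds <- vapply(records, function(r) {
    if (nrow(r$hand) != n) stop("mismatched record lengths")
    prev <- rbind(c(0, 0), r$hand[-n, , drop = FALSE])
    sqrt(rowSums((r$hand - prev)^2)) * 100
  }, numeric(n))
  structure(
    list(mean = rowMeans(speeds),
         sd = apply(speeds, 1, stats::sd),
         n_trials = length(records)),
    class = "pr_velocity_profile"
  )
}

#' Count prominent peaks of a velocity profile
#'
#' A peak is a local maximum whose topographic prominence (height above the
#' highest of the two bounding valleys separating it from higher ground)
#' is at least `min_prominence_frac` of the profile maximum. A smooth
#' natural reach counts 1; a primary-plus-corrective (double-humped) profile
#' counts 2 or more.
#'
#' @param profile A `"pr_velocity_profile"` or numeric speed vector.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   profile maximum (default 0.1).
#' @return Integer peak count.
#' @export
count_velocity_peaks <- function(profile, min_prominence_frac = 0.1) {
  v <- if (inherits(profile, "pr_velocity_profile")) profile$mean else profile
  n <- length(v)
  if (max(v) <= 0) return(0L)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) v[i - 1] else -Inf
    right <- if (i < n) v[i + 1] else -Inf
    v[i] > left && v[i] >= right
  }, logical(1))
  peaks <- which(is_max)
  # prominence = height above the higher of the two bounding saddles; a
  # saddle is the minimum between the peak and the nearest strictly higher
  # point on that side (side minimum if no higher point; -Inf at the border)
  prom <- vapply(peaks, function(p) {
    saddle <- function(idx) {
      if (length(idx) == 0) return(-Inf)
      higher <- which(v[idx] > v[p])
      upto <- if (length(higher) == 0) length(idx) else higher[1]
      min(v[idx[seq_len(upto)]])
    }
    lo_l <- saddle(rev(seq_len(p - 1)))
    lo_r <- saddle(if (p < n) (p + 1):n else integer(0))
    v[p] - max(lo_l, lo_r)
  }, numeric(1))
  sum(prom >= min_prominence_frac * max(v))
}

#' Final-position target error
#'
#' Mean and SD, across trials, of the hand-target distance. The default
#' measure is the final-timestep distance (a distinct quantity from fitness,
#' which sums distance over all timesteps); `"mean_over_timesteps"` averages
#' the distance over the whole trial instead.
#'
#' @param records List of `"pr_trial_record"`.
#' @param measure `"final"` (default) or `"mean_over_timesteps"`.
#' @return List with `mean`, `sd` (degrees) and `per_trial`.
#' @export
target_error <- function(records, measure = c("final", "mean_over_timesteps")) {
  measure <- match.arg(measure)
  per <- vapply(records, function(r) {
    if (measure == "final") r$distance[length(r$distance)]
    else mean(r$distance)
  }, numeric(1))
  list(mean = mean(per), sd = if (length(per) > 1) stats::sd(per) else 0,
       per_trial = per)
}

# Membership masks for the ipsi/contra halves. Vertical axis: upper half =
# grid rows 1..6, lower = rows 6..11 (the middle line belongs to both
# halves, 66 neurons each). Horizontal: left = columns 1..6, right = 6..11.
half_masks <- function(axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  rc <- grid_rc()
  if (axis == "vertical")
    list(a = rc[, "r"] <= 6, b = rc[, "r"] >= 6,   # upper (Up), lower (Down)
         motor = c(1L, 2L))                        # Up, Down
  else
    list(a = rc[, "c"] <= 6, b = rc[, "c"] >= 6,   # left (Left), right (Right)
         motor = c(3L, 4L))                        # Left, Right
}

#' Ipsilateral vs contralateral feedforward/feedback weight summary
#'
#' Splits the PPC grid into the two halves facing a motor-neuron pair
#' (upper/lower for Up/Down, left/right for Left/Right; the middle row or
#' column is included in both halves) and summarizes the weights connecting
#' each half to the corresponding (ipsilateral) vs opposite (contralateral)
#' motor neuron.
#'
#' @param weights A 121 x 4 weight matrix (feedforward `ff_w` or feedback
#'   `fb_w`, both stored PPC-by-motor), or a list of such matrices pooled
#'   across agents.
#' @param axis `"vertical"` (Up/Down pair) or `"horizontal"` (Left/Right).
#' @return Object of class `"pr_connectivity"`: `ipsi_mean`, `ipsi_sem`,
#'   `contra_mean`, `contra_sem`, `n` per group.
#' @export
ipsi_contra_summary <- function(weights, axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  if (!is.list(weights)) weights <- list(weights)
  m <- half_masks(axis)
  ipsi <- contra <- numeric(0)
  for (w in weights) {
    w <- as.matrix(w)
    stopifnot(identical(dim(w), c(N_PPC, N_M1)))
    ipsi <- c(ipsi, w[m$a, m$motor[1]], w[m$b, m$motor[2]])
    contra <- c(contra, w[m$a, m$motor[2]], w[m$b, m$motor[1]])
  }
  structure(
    list(kind = "ipsi_contra", axis = axis,
         ipsi_mean = mean(ipsi), ipsi_sem = stats::sd(ipsi) / sqrt(length(ipsi)),
         contra_mean = mean(contra),
         contra_sem = stats::sd(contra) / sqrt(length(contra)),
         n = length(ipsi), ipsi = ipsi, contra = contra),
    class = "pr_connectivity"
  )
}

#' @export
print.pr_connectivity <- function(x, ...) {
  if (x$kind == "ipsi_contra") {
    cat(sprintf(
      "<pr_connectivity> %s axis: ipsi %.4f +/- %.4f, contra %.4f +/- %.4f (n = %d per group)\n",
      x$axis, x$ipsi_mean, x$ipsi_sem, x$contra_mean, x$contra_sem, x$n))
  } else {
    cat("<pr_connectivity> lateral range bins (mean +/- SEM):\n")
    for (b in names(x$mean))
      cat(sprintf("  %-6s %+.4f +/- %.4f (n = %d)\n",
                  b, x$mean[[b]], x$sem[[b]], x$n[[b]]))
  }
  invisible(x)
}

# Bin labels for all 121 x 121 ordered lateral pairs by connection length:
# short d < 5, medium 5 <= d <= 9, long d > 9 (self-connections are short).
lateral_bins <- function() {
  d <- grid_index_distance()
  b <- matrix("medium", N_PPC, N_PPC)
  b[d < 5] <- "short"
  b[d > 9] <- "long"
  b
}

#' Range-binned lateral weight summary
#'
#' Lateral PPC-to-PPC connections are binned by connection length (Euclidean
#' distance between the pre- and postsynaptic neurons' grid indices):
#' short-range (< 5 index units), medium-range (5 to 9, bounds inclusive)
#' and long-range (> 9). Self-connections fall in the short bin.
#'
#' @param lat_weights A 121 x 121 lateral weight matrix, or a list of them
#'   pooled across agents.
#' @return Object of class `"pr_connectivity"` with per-bin `mean`, `sem`
#'   and `n`.
#' @export
lateral_range_summary <- function(lat_weights) {
  if (!is.list(lat_weights)) lat_weights <- list(lat_weights)
  bins <- lateral_bins()
  vals <- list(short = numeric(0), medium = numeric(0), long = numeric(0))
  for (w in lat_weights) {
    w <- as.matrix(w)
    stopifnot(identical(dim(w), c(N_PPC, N_PPC)))
    for (b in names(vals)) vals[[b]] <- c(vals[[b]], w[bins == b])
  }
  structure(
    list(kind = "lateral_range",
         mean = vapply(vals, mean, numeric(1)),
         sem = vapply(vals, function(x) stats::sd(x) / sqrt(length(x)),
                      numeric(1)),
         n = vapply(vals, length, integer(1))),
    class = "pr_connectivity"
  )
}

#' Direction selectivity of PPC neurons
#'
#' For each PPC neuron, the resultant vector of its per-trial mean firing
#' rates over the 8 target directions: magnitude
#' `|sum_k rbar_k exp(i theta_k)| / sum_k rbar_k` in \[0, 1\] and preferred
#' angle `arg(sum)`. Neurons whose rate never reaches 0.1 on any timestep of
#' any trial are excluded.
#'
#' @param records List of 8 `"pr_trial_record"`, one per target direction
#'   (ordered as [make_targets()]).
#' @param threshold Inclusion threshold on the maximum rate (default 0.1).
#' @return Data frame with columns `neuron`, `included`, `magnitude`,
#'   `angle` (radians; `NA` for excluded neurons).
#' @export
direction_selectivity <- function(records, threshold = 0.1) {
  stopifnot(length(records) == 8)
  angles <- make_targets()$angle
  mean_rates <- vapply(records, function(r) colMeans(r$ppc), numeric(N_PPC))
  max_rates <- apply(vapply(records, function(r) apply(r$ppc, 2, max),
                            numeric(N_PPC)), 1, max)
  included <- max_rates >= threshold
  z <- mean_rates %*% exp(1i * angles)
  mag <- Mod(z) / rowSums(mean_rates)
  ang <- Arg(z) %% (2 * pi)
  data.frame(neuron = seq_len(N_PPC), included = included,
             magnitude = ifelse(included, mag, NA_real_),
             angle = ifelse(included, ang, NA_real_))
}

#' Rank-sum comparison with Bonferroni-style threshold
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) between two samples, flagged significant at
#' `alpha / n_comparisons` (for 6 comparisons the threshold is about 0.0083).
#'
#' @param sample_a,sample_b Numeric samples (each of size >= 2).
#' @param n_comparisons Number of comparisons in the battery (default 6).
#' @param alpha Family-wise level (default 0.05).
#' @return List with `p_value`, `threshold`, `significant`.
#' @export
compare_groups <- function(sample_a, sample_b, n_comparisons = 6,
                           alpha = 0.05) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("both samples must have at least 2 observations")
  p <- stats::wilcox.test(sample_a, sample_b, exact = FALSE,
                          correct = FALSE)$p.value
  thr <- alpha / n_comparisons
  list(p_value = p, threshold = thr, significant = p < thr)
}

#' PPC activity snapshots on the grid
#'
#' Reshapes the 121 PPC rates of selected timesteps to the 11 x 11 grid,
#' together with the change from the trial's first timestep (baseline), the
#' reference used to visualize suppression or elevation across a trial.
#'
#' @param record A `"pr_trial_record"`.
#' @param timesteps Timesteps to extract (default c(1, 3, 9, 17, 25, 35)).
#' @return Named list (one element per timestep) of lists with `rates` and
#'   `delta`, both 11 x 11 matrices (rows = grid rows, top row first).
#' @export
ppc_activity_snapshot <- function(record,
                                  timesteps = c(1, 3, 9, 17, 25, 35)) {
  n <- nrow(record$ppc)
  if (any(timesteps < 1 | timesteps > n)) stop("timestep out of range")
  base <- matrix(record$ppc[1, ], PPC_GRID, PPC_GRID)
  out <- lapply(timesteps, function(t) {
    g <- matrix(record$ppc[t, ], PPC_GRID, PPC_GRID)
    list(rates = g, delta = g - base)
  })
  names(out) <- paste0("t", timesteps)
  out
}

#' Plot a velocity profile
#'
#' Mean instantaneous speed per timestep with a +/-1 SD band.
#'
#' @param x A `"pr_velocity_profile"`.
#' @param ... Passed to [plot()].
#' @export
plot.pr_velocity_profile <- function(x, ...) {
  t <- seq_along(x$mean)
  plot(t, x$mean, type = "l", lwd = 2, ylim = c(0, max(x$mean + x$sd, 300)),
       xlab = "timestep (10 ms)", ylab = "velocity (deg/s)", ...)
  graphics::lines(t, pmax(x$mean - x$sd, 0), lty = 3)
  graphics::lines(t, x$mean + x$sd, lty = 3)
  invisible(x)
}
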