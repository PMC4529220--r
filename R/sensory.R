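#' Sensory projection configuration
#'
#' The fixed (never evolved) topographic projections from the 11x11 visual
#' and proprioceptive input layers onto the 11x11 PPC layer are 2-D cosine
#' tuning curves: the weight from sensory neuron j to PPC neuron i is
#' `f * cos(d / divisor)^g`, with `d` the Euclidean distance between the two
#' neurons' grid indices. The default amplitudes (`f_vision = +2`,
#' `f_prop = -4`) implement a vector-subtraction combination of modalities;
#' the variant `f_vision = +4, f_prop = +4` used for the sensory-weight
#' control experiment is representable by changing these fields.
#'
#' @param f_vision Visual amplitude (default +2).
#' @param f_prop Proprioceptive amplitude (default -4).
#' @param g Cosine exponent (> 0; default 200, giving broad tuning).
#' @param divisor Distance divisor in index units (> 0; default 20).
#' @param grid_rows,grid_cols Sensory/PPC grid dimensions (11 x 11).
#' @return Object of class `"pr_sensory_config"`.
#' @export
sensory_projection_config <- function(f_vision = 2, f_prop = -4,
                                      g = 200, divisor = 20,
                                      grid_rows = 11L, grid_cols = 11L) {
  if (g <= 0) stop("g must be positive")
  if (divisor <= 0) stop("divisor must be positive")
  stopifnot(grid_rows == 11L, grid_cols == 11L)
  structure(
    list(f_vision = f_vision, f_prop = f_prop, g = g, divisor = divisor,
         grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols)),
    class = "pr_sensory_config"
  )
}

#' Build the fixed sensory-to-PPC projection map
#'
#' @param cfg A [sensory_projection_config()].
#' @param modality `"vision"` or `"proprioception"`, selecting the amplitude.
#' @return A 121 x 121 matrix `W` with `W[i, j]` the weight from sensory
#'   neuron j onto PPC neuron i; the peak `|f|` sits at `d = 0`. On the 11x11
#'   grid the cosine argument never reaches pi/2 (max d about 14.14 < 10*pi),
#'   so no rectification is needed.
#' @examples
#' W <- build_sensory_projection(sensory_projection_config(), "vision")
#' W[1, 1]  # 2: cos(0)^g = 1 times the visual amplitude
#' @export
build_sensory_projection <- function(cfg = sensory_projection_config(),
                                     modality = c("vision", "proprioception")) {
  stopifnot(inherits(cfg, "pr_sensory_config"))
  modality <- match.arg(modality)
  f <- if (modality == "vision") cfg$f_vision else cfg$f_prop
  d <- grid_index_distance()
  f * cos(d / cfg$divisor)^cfg$g
}

# Unit activation mass placed on the grid for a continuous position (degrees).
# bilinear: mass split over the <= 4 surrounding nodes (total exactly 1);
# nearest: whole mass on the closest node, degree ties rounded toward zero.
encode_position <- function(pos, encoding = c("bilinear", "nearest")) {
  encoding <- match.arg(encoding)
  x <- pos[1]; y <- pos[2]
  if (any(abs(c(x, y)) > 50)) stop("position outside the [-50, 50] space")
  act <- numeric(N_PPC)
  at <- function(r, c) (c - 1L) * PPC_GRID + r  # column-major index
  if (encoding == "nearest") {
    tiez <- function(v) if (v >= 0) ceiling(v - 0.5) else floor(v + 0.5)
    c0 <- tiez(x / 10) + 6L
    r0 <- 6L - tiez(y / 10)
    act[at(r0, c0)] <- 1
    return(act)
  }
  cf <- x / 10 + 6      # continuous column, 1..11
  rf <- 6 - y / 10      # continuous row, 1..11
  c0 <- min(floor(cf), PPC_GRID - 1L)
  r0 <- min(floor(rf), PPC_GRID - 1L)
  fc <- cf - c0; fr <- rf - r0
  w <- c((1 - fr) * (1 - fc), fr * (1 - fc), (1 - fr) * fc, fr * fc)
  nodes <- c(at(r0, c0), at(r0 + 1, c0), at(r0, c0 + 1), at(r0 + 1, c0 + 1))
  for (k in 1:4) if (w[k] > 0) act[nodes[k]] <- act[nodes[k]] + w[k]
  act
}

#' Encode the proprioceptive hand signal
#'
#' Places one unit of activation on the 11x11 proprioceptive grid at the
#' hand's location; off-node positions are split bilinearly over the nearest
#' nodes so that total mass is exactly 1.
#'
#' @param hand Length-2 numeric, hand position in degrees.
#' @param encoding `"bilinear"` (default) or `"nearest"` (ties toward zero),
#'   for sensitivity checks.
#' @return Numeric vector of length 121 (column-major grid).
#' @export
encode_proprioception <- function(hand, encoding = c("bilinear", "nearest")) {
  encode_position(hand, encoding)
}

#' Encode the visual signal (hand plus target)
#'
#' The visual map is the sum of a unit hand activation and, while the target
#' is visible, a unit target activation; if hand and target occupy the same
#' node the shared node carries activation 2. Hand vision persists for the
#' whole trial in both task modes.
#'
#' @param hand,target Length-2 numeric positions in degrees.
#' @param target_visible Logical; is the target illuminated at this world
#'   timestep?
#' @param encoding See [encode_proprioception()].
#' @return Numeric vector of length 121.
#' @export
encode_vision <- function(hand, target, target_visible = TRUE,
                          encoding = c("bilinear", "nearest")) {
  encoding <- match.arg(encoding)
  act <- encode_position(hand, encoding)
  if (isTRUE(target_visible)) act <- act + encode_position(target, encoding)
  act
}

#' Delayed sensory drive onto the PPC layer
#'
#' At trial timestep `t` the PPC receives the visual map from world timestep
#' `t - (d_vis - 1)` projected through the visual cosine map, plus the
#' proprioceptive map from `t - (d_prop - 1)` through the proprioceptive map.
#' A "D-timestep delay" therefore means first arrival ON timestep D (vision
#' first arrives at t = 9, proprioception at t = 3 under the defaults);
#' pre-trial world timesteps contribute zero.
#'
#' @param history List with components `vision` and `prop`, each a list of
#'   per-world-timestep 121-vectors (as produced inside [run_trial()]).
#' @param t Trial timestep (1-based).
#' @param w_vis,w_prop The two projection maps from
#'   [build_sensory_projection()].
#' @param d_vis,d_prop Delays in timesteps (defaults 9 and 3).
#' @return Numeric vector of length 121, the pre-summed sensory input to each
#'   PPC neuron.
#' @export
delayed_drive <- function(history, t, w_vis, w_prop,
                          d_vis = 9L, d_prop = 3L) {
  drive <- numeric(N_PPC)
  uv <- t - (d_vis - 1L)
  if (uv >= 1L) drive <- drive + as.vector(w_vis %*% history$vision[[uv]])
  up <- t - (d_prop - 1L)
  if (up >= 1L) drive <- drive + as.vector(w_prop %*% history$prop[[up]])
  drive
}
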