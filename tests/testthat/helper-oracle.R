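# Independent oracles, kept deliberately naive and separate from the
# package's own computation paths.

# Minimum summed distance for a 1-D reach by backward dynamic programming
# over discretized positions and per-timestep velocity choices. No movement
# before `first_move`; per-step velocity in [-v_max, v_max] on a `grid_step`
# lattice. `scale` converts the 1-D distance to the 2-D trial distance
# (sqrt(2) for a symmetric diagonal reach).
dp_min_summed_distance <- function(target = 25, n = 50, first_move = 10,
                                   v_max = 2, grid_step = 0.25,
                                   p_max = 30, scale = 1) {
  pos <- seq(0, p_max, by = grid_step)          # reachable positions
  acts <- seq(-v_max, v_max, by = grid_step)    # per-step velocity choices
  np <- length(pos)
  cost <- abs(pos - target) * scale             # incurred after each move
  V <- numeric(np)                              # value after the horizon
  for (t in n:1) {
    if (t < first_move) {
      V <- cost + V                             # forced to stay
    } else {
      Vnew <- numeric(np)
      for (ip in seq_len(np)) {
        p2 <- pos[ip] + acts
        keep <- p2 >= 0 & p2 <= p_max
        ip2 <- round(p2[keep] / grid_step) + 1L
        Vnew[ip] <- min(cost[ip2] + V[ip2])
      }
      V <- Vnew
    }
  }
  V[1]  # start at position 0
}

# Two-sided rank-sum p-value via the normal approximation, computed from
# first principles (no ties expected in the inputs used).
ranksum_p_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U for sample a
  mu <- n1 * n2 / 2
  sd <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  2 * stats::pnorm(-abs((W - mu) / sd))
}

# Explicit per-neuron double-loop synaptic sum.
loop_synaptic_input <- function(w, rates) {
  out <- numeric(nrow(w))
  for (i in seq_len(nrow(w)))
    for (j in seq_len(ncol(w)))
      out[i] <- out[i] + w[i, j] * rates[j]
  out
}

# Direct scalar evaluation of the cosine projection profile.
cosine_weight_oracle <- function(f, d, g = 200, divisor = 20) {
  f * cos(d / divisor)^g
}
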