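#' Sigmoid firing-rate function
#'
#' Rates are generated by `s = 1 / (1 + exp(k * (bias - I)))`, which bounds
#' firing strictly inside (0, 1). The bias shifts the activation range (the
#' midpoint sits at `I = bias`); the gain `k` sets the slope (neural
#' sensitivity).
#'
#' @param I Total synaptic input (any real; the function saturates).
#' @param bias Sigmoid bias, in \[-5, 5\].
#' @param gain Sigmoid gain, in \[0.1, 10\].
#' @return Firing rate(s) in (0, 1); vectorized over `I`.
#' @examples
#' sigmoid_rate(0, bias = 0, gain = 1)   # 0.5 at the midpoint
#' sigmoid_rate(1, bias = 0, gain = 2)   # 1 / (1 + exp(-2))
#' @export
sigmoid_rate <- function(I, bias, gain) {
  1 / (1 + exp(gain * (bias - I)))
}

#' Total synaptic input from the previous timestep's rates
#'
#' `I_i = sum_j w[i, j] * s_j(t-1)`. Used for every connection set: the
#' update is synchronous, so all terms read rates from the previous timestep.
#'
#' @param weights Post-by-pre weight matrix.
#' @param rates Presynaptic rate vector from the previous timestep.
#' @return Per-postsynaptic-neuron input vector.
#' @export
synaptic_input <- function(weights, rates) {
  weights <- as.matrix(weights)
  if (ncol(weights) != length(rates))
    stop("weight columns (", ncol(weights),
         ") do not match presynaptic rates (", length(rates), ")")
  as.vector(weights %*% rates)
}

#' Baseline network state
#'
#' Timestep 1 of a trial starts from baseline firing: zero external input
#' propagated once through the sigmoid, i.e. `1 / (1 + exp(k * bias))` per
#' layer. Deterministic in the genome.
#'
#' @param genome A `"pr_genome"`.
#' @return Object of class `"pr_state"` with `ppc_rates` (121), `m1_rates`
#'   (4, ordered Up, Down, Left, Right) and `timestep = 0`.
#' @export
init_state <- function(genome) {
  stopifnot(inherits(genome, "pr_genome"))
  structure(
    list(ppc_rates = rep(sigmoid_rate(0, genome$ppc_bias, genome$ppc_gain), N_PPC),
         m1_rates = rep(sigmoid_rate(0, genome$m1_bias, genome$m1_gain), N_M1),
         timestep = 0L),
    class = "pr_state"
  )
}

#' One synchronous network update
#'
#' Every term reads rates from the previous timestep: PPC input is the
#' delayed sensory drive plus (per architecture) lateral and feedback
#' contributions; motor (PMd/M1) input is the feedforward PPC drive only.
#' This gives a one-timestep transmission lag from PPC to the motor layer.
#'
#' @param state A `"pr_state"` from [init_state()] or a previous `step()`.
#' @param genome The agent's `"pr_genome"`.
#' @param ppc_sensory_drive Pre-summed delayed sensory input to each PPC
#'   neuron (length 121), e.g. from [delayed_drive()].
#' @return The updated `"pr_state"` with `timestep` incremented.
#' @export
step <- function(state, genome, ppc_sensory_drive) {
  stopifnot(inherits(state, "pr_state"), inherits(genome, "pr_genome"),
            length(ppc_sensory_drive) == N_PPC)
  ppc_in <- ppc_sensory_drive
  if (genome$arch$has_lateral)
    ppc_in <- ppc_in + synaptic_input(genome$lat_w, state$ppc_rates)
  if (genome$arch$has_feedback)
    ppc_in <- ppc_in + synaptic_input(genome$fb_w, state$m1_rates)
  m1_in <- synaptic_input(t(genome$ff_w), state$ppc_rates)
  structure(
    list(ppc_rates = sigmoid_rate(ppc_in, genome$ppc_bias, genome$ppc_gain),
         m1_rates = sigmoid_rate(m1_in, genome$m1_bias, genome$m1_gain),
         timestep = state$timestep + 1L),
    class = "pr_state"
  )
}
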