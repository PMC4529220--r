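# Shared fixtures, all built in code.

SIM <- sim_config()

seeded_genome <- function(arch, seed) {
  set.seed(seed)
  random_genome(arch)
}

# Minimal trial-record stand-in for analysis functions that only need some
# of the fields (hand paths, PPC rates), built from prescribed matrices.
fake_record <- function(hand = NULL, ppc = NULL, m1 = NULL,
                        target = c(25, 0), mode = "VG") {
  n <- if (!is.null(hand)) nrow(hand) else nrow(ppc)
  if (is.null(hand)) hand <- matrix(0, n, 2)
  if (is.null(ppc)) ppc <- matrix(0.5, n, 121)
  if (is.null(m1)) m1 <- matrix(0.5, n, 4)
  dist <- sqrt((hand[, 1] - target[1])^2 + (hand[, 2] - target[2])^2)
  structure(list(hand = hand, ppc = ppc, m1 = m1, distance = dist,
                 target = c(x = target[1], y = target[2]),
                 mode = task_mode(mode)),
            class = "pr_trial_record")
}

# Straight-line records at constant speed toward each of the 8 targets.
steady_records <- function(speed = 2, n = 50) {
  tg <- make_targets()
  lapply(1:8, function(k) {
    u <- c(tg$x[k], tg$y[k]) / sqrt(tg$x[k]^2 + tg$y[k]^2)
    hand <- outer(seq_len(n) * speed, u)
    fake_record(hand = hand, target = c(tg$x[k], tg$y[k]))
  })
}
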