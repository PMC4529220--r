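test_that("velocity profiles convert per-timestep displacement to deg/s", {
  vp <- velocity_profile(steady_records(speed = 2))
  expect_length(vp$mean, 50)
  expect_equal(vp$mean, rep(200, 50))
  expect_equal(vp$sd, rep(0, 50))
  # stationary records give all zeros
  vp0 <- velocity_profile(list(fake_record(hand = matrix(0, 50, 2))))
  expect_equal(vp0$mean, rep(0, 50))
  # hand-built two-trial fixture vs manual per-step arithmetic
  h1 <- cbind(c(1, 3, 3), c(0, 0, 4))   # steps 1, 2, 4
  h2 <- cbind(c(0, 0, 3), c(2, 2, 6))   # steps 2, 0, 5
  vp2 <- velocity_profile(list(fake_record(hand = h1),
                               fake_record(hand = h2)))
  expect_equal(vp2$mean, c(150, 100, 450))
  expect_equal(vp2$sd, apply(cbind(c(1, 2, 4), c(2, 0, 5)) * 100, 1, sd))
  expect_error(velocity_profile(list(fake_record(hand = h1),
                                     fake_record(hand = matrix(0, 5, 2)))),
               "mismatched")
})

test_that("velocity peak counting distinguishes single from double humps", {
  t <- 1:50
  single <- exp(-(t - 20)^2 / 50) * 200
  expect_identical(count_velocity_peaks(single), 1L)
  double <- exp(-(t - 15)^2 / 20) * 200 + exp(-(t - 32)^2 / 20) * 120
  expect_identical(count_velocity_peaks(double), 2L)
  # a tiny ripple below the prominence threshold does not count
  rippled <- single + c(rep(0, 34), 3, 0, 3, rep(0, 13))
  expect_identical(count_velocity_peaks(rippled), 1L)
  expect_identical(count_velocity_peaks(rep(0, 50)), 0L)
  # the optimal trajectory's profile: flat cap from movement onset, then 0
  tg <- make_targets()
  recs <- lapply(1:8, function(n)
    fake_record(hand = optimal_trajectory(tg[n, ]),
                target = c(tg$x[n], tg$y[n])))
  vp <- velocity_profile(recs)
  expect_identical(count_velocity_peaks(vp), 1L)
  expect_equal(max(vp$mean), mean(c(rep(200, 4), rep(200 * sqrt(2), 4))))
  expect_true(all(vp$mean[1:9] == 0) && all(vp$mean[24:50] == 0))
})

test_that("target error summarizes final-position accuracy", {
  tg <- make_targets()
  on_target <- lapply(1:8, function(n) {
    fake_record(hand = matrix(c(tg$x[n], tg$y[n]), 50, 2, byrow = TRUE),
                target = c(tg$x[n], tg$y[n]))
  })
  te <- target_error(on_target)
  expect_equal(te$mean, 0)
  expect_equal(te$sd, 0)
  # the never-moving agent: closed-form mean over the 8 eccentricities
  still <- lapply(1:8, function(n)
    fake_record(hand = matrix(0, 50, 2), target = c(tg$x[n], tg$y[n])))
  te <- target_error(still)
  expect_equal(te$mean, (4 * 25 + 4 * 25 * sqrt(2)) / 8)
  expect_equal(te$mean, 30.18, tolerance = 1e-3)
  expect_equal(target_error(still[1])$sd, 0)
  # alternative measure averages over timesteps
  expect_equal(target_error(still, "mean_over_timesteps")$mean, te$mean)
})

test_that("ipsi/contra grouping matches its definition", {
  # constructed fixture: upper-half rows positive to Up, lower negative
  rc <- cbind(r = (0:120) %% 11 + 1, c = (0:120) %/% 11 + 1)
  w <- matrix(0, 121, 4)
  w[rc[, "r"] <= 6, 1] <- 0.5    # upper half (middle row included) -> Up
  w[rc[, "r"] >= 6, 1] <- -0.5   # lower half -> Up (middle row overwritten)
  w[rc[, "r"] == 6, 1] <- 0.5    # keep the shared middle row positive
  s <- ipsi_contra_summary(w, "vertical")
  expect_identical(s$n, 132L)    # 66 neurons x 2 halves
  expect_equal(s$ipsi_mean, mean(c(rep(0.5, 66), rep(0, 66))))
  # all-zero weights
  s0 <- ipsi_contra_summary(matrix(0, 121, 4), "horizontal")
  expect_equal(s0$ipsi_mean, 0)
  expect_equal(s0$contra_mean, 0)
  # random weights against an explicit double-loop regrouping
  set.seed(8)
  w <- matrix(runif(484, -1, 1), 121, 4)
  s <- ipsi_contra_summary(w, "horizontal")
  ipsi <- contra <- c()
  for (n in 1:121) {
    col <- rc[n, "c"]
    if (col <= 6) { ipsi <- c(ipsi, w[n, 3]); contra <- c(contra, w[n, 4]) }
    if (col >= 6) { ipsi <- c(ipsi, w[n, 4]); contra <- c(contra, w[n, 3]) }
  }
  expect_equal(s$ipsi_mean, mean(ipsi))
  expect_equal(s$contra_mean, mean(contra))
  expect_equal(s$ipsi_sem, sd(ipsi) / sqrt(length(ipsi)))
})

test_that("lateral bins partition all ordered pairs at the stated bounds", {
  # neuron at grid (1,1) is index 1; (4,4) is index 3*11+4 = 37 (d = sqrt(18))
  # (4,5) is index 4*11+4 = 48 (d = 5); (8,8) is index 7*11+8 = 85 (d ~ 9.9)
  w <- matrix(0, 121, 121)
  w[37, 1] <- 1     # short
  w[48, 1] <- 10    # medium (inclusive lower bound)
  w[85, 1] <- 100   # long
  s <- lateral_range_summary(w)
  expect_identical(sum(s$n), 121L * 121L)
  expect_equal(s$mean[["short"]] * s$n[["short"]], 1)
  expect_equal(s$mean[["medium"]] * s$n[["medium"]], 10)
  expect_equal(s$mean[["long"]] * s$n[["long"]], 100)
  # bin counts against an explicit brute-force count over index pairs
  rc <- cbind(r = (0:120) %% 11 + 1, c = (0:120) %/% 11 + 1)
  cnt <- c(short = 0L, medium = 0L, long = 0L)
  for (i in 1:121) for (j in 1:121) {
    d <- sqrt(sum((rc[i, ] - rc[j, ])^2))
    b <- if (d < 5) "short" else if (d <= 9) "medium" else "long"
    cnt[b] <- cnt[b] + 1L
  }
  expect_identical(s$n, cnt)
})

test_that("direction selectivity uses the resultant vector with the 0.1 gate", {
  base <- matrix(0.001, 50, 121)
  recs <- lapply(1:8, function(k) fake_record(ppc = base))
  # neuron 1 fires only on the rightward trial (trial 1, angle 0)
  recs[[1]]$ppc[, 1] <- 0.8
  # neuron 2 fires equally on all 8 trials
  for (k in 1:8) recs[[k]]$ppc[, 2] <- 0.5
  # neuron 3 peaks at 0.05: excluded
  recs[[1]]$ppc[, 3] <- 0.05
  dsi <- direction_selectivity(recs)
  expect_true(dsi$included[1])
  expect_equal(dsi$magnitude[1], 1, tolerance = 0.02)
  expect_equal(dsi$angle[1], 0, tolerance = 0.02)
  expect_true(dsi$included[2])
  expect_equal(dsi$magnitude[2], 0, tolerance = 1e-9)
  expect_false(dsi$included[3])
  expect_true(is.na(dsi$magnitude[3]))
  expect_true(all(dsi$magnitude[dsi$included] >= 0 &
                  dsi$magnitude[dsi$included] <= 1))
})

test_that("rank-sum comparisons match an independent statistic and threshold", {
  set.seed(12)
  a <- rnorm(100)
  b <- rnorm(100, mean = 3)
  res <- compare_groups(a, b, n_comparisons = 6)
  expect_lt(res$p_value, 1e-3)
  expect_true(res$significant)
  expect_equal(res$threshold, 0.05 / 6)
  expect_equal(res$threshold, 0.0083, tolerance = 1e-2)
  # agreement with a from-scratch normal-approximation rank-sum p
  expect_equal(res$p_value, ranksum_p_oracle(a, b), tolerance = 1e-9)
  c <- rnorm(50); d <- c + rnorm(50, sd = 1e-12)
  near <- compare_groups(c, d)
  expect_gt(near$p_value, 0.9)
  expect_false(near$significant)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("PPC snapshots reshape rates and reference the trial baseline", {
  g <- seeded_genome("LAT", 17)
  rec <- run_trial(g, 1, "VG", SIM)
  snaps <- ppc_activity_snapshot(rec)
  expect_named(snaps, c("t1", "t3", "t9", "t17", "t25", "t35"))
  expect_equal(snaps$t1$delta, matrix(0, 11, 11))
  expect_equal(as.vector(snaps$t17$rates), rec$ppc[17, ])
  expect_equal(snaps$t25$delta, snaps$t25$rates - snaps$t1$rates)
  # constant-rate record has all-zero deltas
  snaps0 <- ppc_activity_snapshot(fake_record(ppc = matrix(0.3, 50, 121)),
                                  timesteps = c(1, 50))
  expect_equal(snaps0$t50$delta, matrix(0, 11, 11))
  expect_error(ppc_activity_snapshot(rec, timesteps = 51), "out of range")
})
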