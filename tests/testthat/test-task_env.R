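test_that("the eight targets sit at the documented eccentricities", {
  tg <- make_targets()
  expect_identical(nrow(tg), 8L)
  ecc <- sqrt(tg$x^2 + tg$y^2)
  expect_equal(ecc[c(1, 3, 5, 7)], rep(25, 4))
  expect_equal(ecc[c(2, 4, 6, 8)], rep(25 * sqrt(2), 4))
  expect_equal(tg$angle, (0:7) * pi / 4)
  # deterministic order: trial 1 rightward, trial 3 upward
  expect_equal(c(tg$x[1], tg$y[1]), c(25, 0))
  expect_equal(c(tg$x[3], tg$y[3]), c(0, 25))
})

test_that("sensory encoding places unit mass, bilinearly or nearest", {
  a <- encode_proprioception(c(0, 0))
  expect_equal(sum(a), 1)
  expect_equal(a[(6 - 1) * 11 + 6], 1)   # center node (r = 6, c = 6)
  # the 25-degree target sits between nodes at 20 and 30 degrees
  a <- encode_proprioception(c(25, 0))
  expect_equal(sum(a), 1)
  expect_equal(a[(8 - 1) * 11 + 6], 0.5)  # x = 20 (c = 8), center row
  expect_equal(a[(9 - 1) * 11 + 6], 0.5)  # x = 30 (c = 9)
  # mass conservation anywhere in the space
  set.seed(1)
  for (i in 1:20) {
    p <- runif(2, -50, 50)
    expect_equal(sum(encode_proprioception(p)), 1)
    expect_equal(sum(encode_vision(p, c(0, 25), TRUE)), 2)
  }
  # nearest encoding: whole mass on one node, ties rounded toward zero
  a <- encode_proprioception(c(25, 0), encoding = "nearest")
  expect_equal(a[(8 - 1) * 11 + 6], 1)    # 25 -> 20 degrees
  a <- encode_proprioception(c(-25, 0), encoding = "nearest")
  expect_equal(a[(4 - 1) * 11 + 6], 1)    # -25 -> -20 degrees
  expect_error(encode_proprioception(c(60, 0)), "outside")
})

test_that("vision sums hand and target maps; overlap gives 2", {
  a <- encode_vision(c(0, 0), c(0, 0), TRUE)
  expect_equal(a[(6 - 1) * 11 + 6], 2)
  # invisible target contributes nothing
  expect_equal(encode_vision(c(10, 0), c(0, 25), FALSE),
               encode_proprioception(c(10, 0)))
})

test_that("delayed drive reflects the documented arrival timesteps", {
  hand0 <- c(0, 0)
  history <- list(vision = list(), prop = list())
  for (t in 1:12) {
    history$vision[[t]] <- encode_vision(hand0, c(25, 0), TRUE)
    history$prop[[t]] <- encode_proprioception(hand0)
  }
  w_vis <- SIM$w_vis; w_prop <- SIM$w_prop
  # before the 3rd timestep nothing has arrived at all
  expect_equal(delayed_drive(history, 2, w_vis, w_prop), rep(0, 121))
  # timestep 3: proprioception from world timestep 1 only
  expect_equal(delayed_drive(history, 3, w_vis, w_prop),
               as.vector(w_prop %*% history$prop[[1]]))
  # timestep 8: still blind to vision
  expect_equal(delayed_drive(history, 8, w_vis, w_prop),
               as.vector(w_prop %*% history$prop[[6]]))
  # timestep 9: vision from world timestep 1 (target onset) arrives
  expect_equal(delayed_drive(history, 9, w_vis, w_prop),
               as.vector(w_vis %*% history$vision[[1]] +
                         w_prop %*% history$prop[[7]]))
})

test_that("population-vector decode matches the printed caps", {
  expect_equal(decode_population_vector(c(0, 0, 0, 1)), c(2, 0))
  expect_equal(decode_population_vector(c(1, 0, 0, 1)), c(2, 2))
  expect_equal(sqrt(sum(decode_population_vector(c(1, 0, 0, 1))^2)),
               2 * sqrt(2))
  expect_equal(decode_population_vector(c(0.4, 0.4, 0.4, 0.4)), c(0, 0))
  expect_equal(decode_population_vector(c(0, 1, 1, 0), v = 3), c(-3, -3))
})

test_that("a trial records 50 post-movement positions and distances", {
  z <- fixture_genomes("FF")$zero
  rec <- run_trial(z, 1, "VG", SIM)
  expect_identical(nrow(rec$hand), 50L)
  expect_length(rec$distance, 50)
  # all motor rates equal -> zero decode -> the hand never moves
  expect_equal(rec$hand, matrix(0, 50, 2), ignore_attr = TRUE)
  expect_equal(sum(rec$distance), 50 * 25)
  # distances recomputable from stored positions
  g <- seeded_genome("FF", 5)
  rec <- run_trial(g, 2, "VG", SIM)
  expect_equal(rec$distance,
               sqrt((rec$hand[, 1] - rec$target[1])^2 +
                    (rec$hand[, 2] - rec$target[2])^2))
})

test_that("compiled and reference engines agree", {
  for (a in c("FF", "FBLAT")) {
    g <- seeded_genome(a, 13)
    r1 <- run_trial(g, 4, "MG", SIM, engine = "cpp")
    r2 <- run_trial(g, 4, "MG", SIM, engine = "r")
    expect_equal(r1$hand, r2$hand, tolerance = 1e-9)
    expect_equal(r1$ppc, r2$ppc, tolerance = 1e-9)
    expect_equal(r1$distance, r2$distance, tolerance = 1e-9)
  }
})

test_that("VG and MG trials share the delay-determined prefix", {
  g <- seeded_genome("LAT", 21)
  vg <- run_trial(g, 2, "VG", SIM)
  mg <- run_trial(g, 2, "MG", SIM)
  # target offset (world t = 6) reaches PPC at t = 14, motor/hand at t = 15
  expect_identical(vg$hand[1:14, ], mg$hand[1:14, ])
  expect_identical(vg$ppc[1:13, ], mg$ppc[1:13, ])
  expect_false(isTRUE(all.equal(vg$ppc[14, ], mg$ppc[14, ])))
  expect_false(identical(vg$hand[15, ], mg$hand[15, ]))
})

test_that("the never-moving agent's fitness matches the closed form", {
  z <- fixture_genomes("FF")$zero
  f <- evaluate_agent(z, "VG", SIM)
  expect_equal(f$raw, 4 * 50 * 25 + 4 * 50 * 25 * sqrt(2))
  expect_equal(f$raw, 12071.07, tolerance = 1e-6)
  expect_equal(f$corrected, 8507.7, tolerance = 1e-4)
  expect_equal(sum(f$per_trial), f$raw)
  # determinism
  expect_identical(f, evaluate_agent(z, "VG", SIM))
  # engines agree on fitness too
  g <- seeded_genome("FB", 2)
  expect_equal(evaluate_agent(g, "MG", SIM)$raw,
               evaluate_agent(g, "MG", SIM, engine = "r")$raw,
               tolerance = 1e-9)
})

test_that("optimal fitness bound matches closed forms and brute-force search", {
  tg <- make_targets()
  # single cardinal trial: 9 blind samples + capped straight approach
  cardinal <- optimal_fitness_bound(tg[1, ])
  expect_equal(cardinal, 9 * 25 + sum(25 - 2 * (1:12)))
  expect_equal(cardinal, 369.0)
  diagonal <- optimal_fitness_bound(tg[2, ])
  expect_equal(diagonal, sqrt(2) * 369, tolerance = 1e-9)
  expect_equal(diagonal, 521.85, tolerance = 1e-4)
  # independent dynamic-programming search over velocity schedules
  expect_equal(cardinal, dp_min_summed_distance(target = 25))
  expect_equal(diagonal,
               dp_min_summed_distance(target = 25, scale = sqrt(2)),
               tolerance = 1e-9)
  expect_equal(optimal_fitness_bound(), 4 * cardinal + 4 * diagonal)
  # an agent following the optimal trajectory scores corrected fitness 0
  total <- 0
  for (n in 1:8) {
    traj <- optimal_trajectory(tg[n, ])
    total <- total + sum(sqrt((traj[, 1] - tg$x[n])^2 +
                              (traj[, 2] - tg$y[n])^2))
  }
  expect_equal(total - optimal_fitness_bound(), 0)
})

test_that("trial distances never exceed the start distance by the speed cap rule", {
  # decode bound: per-axis speed < 2, so step length < 2*sqrt(2)
  g <- seeded_genome("FBLAT", 31)
  rec <- run_trial(g, 2, "VG", SIM)
  steps <- diff(rbind(c(0, 0), rec$hand))
  expect_true(all(sqrt(rowSums(steps^2)) <= 2 * sqrt(2)))
})
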