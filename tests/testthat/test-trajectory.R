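# Markov-chain trajectory generation, smoothing and pair criteria.

test_that("chain configuration spans 181 one-degree states with stochastic rows", {
  cfg <- markovChainConfig()
  expect_identical(markovStateCount(cfg), 181L)
  P <- transitionMatrix(cfg)
  expect_equal(dim(P), c(181, 181))
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  # local random walk: sub- and super-diagonal mass everywhere
  expect_true(all(P[cbind(2:181, 1:180)] > 0))
  expect_true(all(P[cbind(1:180, 2:181)] > 0))
})

test_that("an absorbing kernel pins the trajectory at its start state", {
  cfg <- markovChainConfig(stepSpan = 0, kernelProfile = 1)
  tr <- generateMarkovTrajectory(cfg, 12, startStateDeg = 0)
  expect_true(all(azimuth(tr) == 0))
})

test_that("generation is deterministic per seed and stays on the grid", {
  cfg <- markovChainConfig()
  t1 <- generateMarkovTrajectory(cfg, 60, seed = 7L)
  t2 <- generateMarkovTrajectory(cfg, 60, seed = 7L)
  expect_identical(azimuth(t1), azimuth(t2))
  for (s in 1:1000) {
    tr <- generateMarkovTrajectory(cfg, 8, seed = s)
    a <- azimuth(tr)
    expect_true(all(a >= -90 & a <= 90))
    expect_true(all(a == round(a)))
  }
})

test_that("a long ergodic run visits all 181 states", {
  tr <- generateMarkovTrajectory(markovChainConfig(), 60000, seed = 1L)
  expect_identical(length(unique(azimuth(tr))), 181L)
})

test_that("a zero-mass kernel is rejected as unnormalizable", {
  cfg <- markovChainConfig()
  cfg@kernelProfile <- rep(0, 7)
  expect_error(generateMarkovTrajectory(cfg, 10), "normalizable")
})

test_that("smoothing stretches output to span the full half plane at 10 Hz", {
  tr <- generateMarkovTrajectory(markovChainConfig(), 25, seed = 3L)
  up <- smoothStretchUpsample(tr)
  expect_equal(min(azimuth(up)), -90)
  expect_equal(max(azimuth(up)), 90)
  expect_equal(samplingRate(up), 10)
  expect_equal(length(azimuth(up)), durationS(tr) * 10, tolerance = 1)
})

test_that("constant input skips the stretch with a warning", {
  tr <- new("Trajectory", azimuthDeg = rep(10, 20), rateHz = 0.5)
  expect_warning(up <- smoothStretchUpsample(tr), "stretch skipped")
  expect_true(all(azimuth(up) == 10))
})

test_that("upsampling is piecewise linear and recovers node samples", {
  # ramp across the half plane: smoothing and stretching keep it a ramp
  n <- 21
  tr <- new("Trajectory", azimuthDeg = seq(-90, 90, length.out = n),
            rateHz = 0.5)
  up <- smoothStretchUpsample(tr, smoothWindow = 1)
  tNodes <- (seq_len(n) - 1) / 0.5
  expect_equal(azimuthAt(up, tNodes[1:(n - 1)]),
               azimuth(tr)[1:(n - 1)], tolerance = 1e-9)
  # intermediate 10 Hz points sit on the connecting line segments
  tMid <- tNodes[1] + c(0.4, 0.8, 1.2)
  slope <- diff(azimuth(tr))[1] / 2
  expect_equal(azimuthAt(up, tMid), -90 + slope * tMid, tolerance = 1e-9)
})

test_that("pair criteria handle constants, identical and mirrored ramps", {
  pc <- checkPairCriteria(pairOf(rep(90, 100), rep(-90, 100)), 3, 5)
  expect_equal(pc@criteriaReport$measured[1:2], c(180, 180))
  expect_equal(pc@criteriaReport$measured[3], 0)   # variance-zero guard
  expect_true(pc@criteriaReport$pass[4])

  same <- checkPairCriteria(pairOf(seq(-90, 90, length.out = 100),
                                   seq(-90, 90, length.out = 100)), 3, 5)
  expect_equal(same@criteriaReport$measured[1:2], c(0, 0))
  expect_equal(same@criteriaReport$measured[3], 1)
  expect_false(any(same@criteriaReport$pass))

  ramp <- seq(-90, 90, length.out = 100)
  mir <- checkPairCriteria(pairOf(ramp, -ramp), 3, 5)
  expect_equal(mir@criteriaReport$measured[3], -1)
  expect_true(mir@criteriaReport$pass[3])
})

test_that("out-of-support test times are rejected", {
  expect_error(checkPairCriteria(pairOf(rep(0, 10), rep(0, 10)), 3, 99),
               "outside trajectory support")
})

test_that("joint-entropy selection matches the closed form and brute force", {
  cent <- seq(-80, 80, by = 20)
  g <- expand.grid(a = cent, b = cent)   # all 81 bins once
  unif <- pairOf(g$a, g$b)
  conc <- pairOf(rep(0, 81), rep(0, 81))
  expect_equal(jointEntropyBits(list(unif)), log2(81))
  expect_equal(jointEntropyBits(list(conc)), 0)
  expect_identical(selectMaxEntropySet(list(list(conc), list(unif))), 2L)
  # trivial cases: single candidate, tie-break by lowest index
  expect_identical(selectMaxEntropySet(list(list(conc))), 1L)
  expect_identical(selectMaxEntropySet(list(list(unif), list(unif))), 1L)
  expect_error(selectMaxEntropySet(list()), "empty")
  # brute-force agreement on small random sets
  set.seed(42)
  sets <- lapply(1:4, function(i)
    lapply(seq_len(sample(1:5, 1)), function(j)
      pairOf(runif(50, -90, 90), runif(50, -90, 90))))
  brute <- vapply(sets, function(s) {
    counts <- matrix(0, 9, 9)
    for (p in s) {
      ia <- pmin(9, floor((p@trajA@azimuthDeg + 90) / 20) + 1)
      ib <- pmin(9, floor((p@trajB@azimuthDeg + 90) / 20) + 1)
      for (k in seq_along(ia)) counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1
    }
    pr <- counts / sum(counts); pr <- pr[pr > 0]
    -sum(pr * log2(pr))
  }, 0)
  expect_equal(vapply(sets, jointEntropyBits, 0), brute, tolerance = 1e-12)
  expect_identical(selectMaxEntropySet(sets),
                   as.integer(which.max(brute)))
})

test_that("generated pairs satisfy all three criteria", {
  pair <- generateTrajectoryPair(40, seed = 5L)
  expect_true(pair@criteriaReport$pass[4])
  expect_equal(samplingRate(pair@trajA), 10)
})
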