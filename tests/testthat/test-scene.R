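# Scene assembly: speech-like synthesis, repeat insertion, spatialization
# and mixing.

test_that("speech-like utterances are deterministic with valid word intervals", {
  prof <- talkerProfile(120)
  u1 <- synthSpeechlikeUtterance(prof, 4, rep(0.4, 5), seed = 3L)
  u2 <- synthSpeechlikeUtterance(prof, 4, rep(0.4, 5), seed = 3L)
  expect_identical(u1$wave, u2$wave)
  expect_identical(nrow(u1$words), 5L)
  expect_true(all(u1$words$offset_s - u1$words$onset_s >= 0.3))
  rms <- sqrt(mean(u1$wave^2))
  expect_gt(rms, 0.05)
  expect_lt(rms, 0.5)
})

test_that("repeat planning follows the count arithmetic", {
  plan <- planRepeatInsertion(44, seed = 5L)
  expect_identical(plan$nRepeats, round(44 / 7))
  expect_identical(nrow(plan$attended), 6L)
  expect_identical(nrow(plan$unattended), 6L)
  plan50 <- planRepeatInsertion(50, seed = 5L)
  expect_equal(nrow(plan50$attended), round(50 / 7))
})

test_that("a generated scene passes the full audit", {
  audit <- auditTrialScene(fixtureScene())
  expect_true(all(audit$pass), info = paste(capture.output(print(
    audit[!audit$pass, ])), collapse = "\n"))
})

test_that("same-stream and cross-stream repeat gaps respect the bounds", {
  ev <- repeatEvents(fixtureScene())
  e1 <- ev[ev$stream == 1, ]; e2 <- ev[ev$stream == 2, ]
  gaps <- c(diff(e1$onset_s), diff(e2$onset_s))
  expect_true(all(gaps >= 5.5 - 1e-6 & gaps <= 9.5 + 1e-6))
  expect_gte(min(abs(outer(e1$onset_s, e2$onset_s, "-"))), 2.5 - 1e-6)
  expect_true(min(ev$onset_s) >= 5 && min(ev$onset_s) <= 8)
})

test_that("scene regeneration from its seed is bit-identical", {
  s1 <- fixtureScene()
  s2 <- buildTrialScene(seed = s1@meta$seed, durationS = s1@meta$durationS)
  expect_identical(s1@mixture@left, s2@mixture@left)
  expect_identical(s1@mixture@right, s2@mixture@right)
})

test_that("spatializer is symmetric at zero azimuth and conserves energy", {
  set.seed(1)
  x <- rnorm(16000)
  bs0 <- spatialize(x, constTrajectory(0, rateHz = 10, n = 11), 16000)
  expect_lt(max(abs(bs0@left - bs0@right)), 1e-6)
  pw <- (mean(bs0@left^2) + mean(bs0@right^2)) / 2
  expect_lt(abs(10 * log10(pw / mean(x^2))), 1)
})

test_that("measured interaural delay matches the Woodworth closed form", {
  t <- (0:15999) / 16000
  tone <- sin(2 * pi * 500 * t)
  bs <- spatialize(tone, constTrajectory(90, n = 11), 16000)
  phaseAt <- function(x) Arg(sum(x * exp(-2i * pi * 500 * t)))
  itd <- (phaseAt(bs@left) - phaseAt(bs@right)) / (2 * pi * 500)
  expect_equal(itd, woodworthItd(90), tolerance = 5e-3)
  expect_gt(itd, 0)   # left channel leads for positive (left) azimuth
})

test_that("spatializer ITD is odd-symmetric in azimuth", {
  t <- (0:15999) / 16000
  tone <- sin(2 * pi * 500 * t)
  for (az in c(20, 45, 70, 90)) {
    phaseAt <- function(x) Arg(sum(x * exp(-2i * pi * 500 * t)))
    bsP <- spatialize(tone, constTrajectory(az, n = 11), 16000)
    bsN <- spatialize(tone, constTrajectory(-az, n = 11), 16000)
    itdP <- (phaseAt(bsP@left) - phaseAt(bsP@right)) / (2 * pi * 500)
    itdN <- (phaseAt(bsN@left) - phaseAt(bsN@right)) / (2 * pi * 500)
    expect_equal(itdP, -itdN, tolerance = 1 / 16000)
  }
})

test_that("azimuths beyond the frontal half plane are rejected", {
  bad <- new("Trajectory", azimuthDeg = rep(90, 11), rateHz = 10)
  slot(bad, "azimuthDeg", check = FALSE) <- rep(120, 11)
  expect_error(spatialize(rnorm(100), bad, 16000), "frontal half plane")
})

test_that("mixing hits the requested noise level and exact component sum", {
  sc <- fixtureScene()
  pConv <- mean((sc@conv1@left^2 + sc@conv1@right^2)[
    sc@conv1@left != 0 | sc@conv1@right != 0] / 2)
  pNoise <- mean(sc@noise@left^2)
  expect_equal(10 * log10(pConv / pNoise), -sc@noiseLevelDb, tolerance = 0.1)
  expect_identical(sc@mixture@left,
                   sc@conv1@left + sc@conv2@left + sc@noise@left)
  expect_error(
    mixScene(sc@conv1, sc@conv2, sc@noise@left, noiseLevelDb = -6,
             trajectories = sc@trajectories, scripts = sc@scripts),
    "-9 or -12")
})

test_that("the uncued conversation onset lag is exact at sample resolution", {
  sc <- fixtureScene()
  on1 <- which(sc@meta$mono1 != 0)[1]
  on2 <- which(sc@meta$mono2 != 0)[1]
  expect_identical(on2 - on1, as.integer(round(3 * 16000)))
})
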