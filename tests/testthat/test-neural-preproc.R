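# Preprocessing chain: reference montage, line-noise notch, high-gamma
# envelopes and speech-responsive electrode selection.

test_that("common average reference removes shared components only", {
  set.seed(1)
  x <- rnorm(4000)
  # zero-mean montage {x, -x}: CAR leaves it unchanged
  m <- rbind(x, -x)
  carred <- sweep(m, 2, colMeans(m))
  expect_equal(carred, m)
  # a common DC offset is removed exactly by CAR within standardize
  fs <- 1000
  base <- matrix(rnorm(2 * fs * 6), 2)
  recA <- neuralRecording(base, fs)
  recB <- neuralRecording(base + 50, fs)   # shared offset on all channels
  outA <- standardizeRecording(recA)
  outB <- standardizeRecording(recB)
  expect_equal(outA@data, outB@data, tolerance = 1e-9)
})

test_that("single-channel recordings cannot be re-referenced", {
  rec <- neuralRecording(matrix(rnorm(4000), 1), 1000)
  expect_error(standardizeRecording(rec), "at least 2 channels")
})

test_that("the notch attenuates 60 Hz by at least 40 dB", {
  t <- (0:(400 * 10 - 1)) / 400
  for (f in c(60, 120, 180)) {
    y <- sin(2 * pi * f * t)
    yn <- cocktailAAD:::notchLineNoise(rbind(y, -y), 400)
    att <- 20 * log10(sqrt(mean(yn[1, 400:3600]^2)) / sqrt(mean(y^2)))
    expect_lt(att, -40)
  }
})

test_that("standardization lands at 400 Hz for both hardware rates", {
  for (fs in c(1024, 1526)) {
    rec <- neuralRecording(matrix(rnorm(2 * fs * 4), 2), fs)
    out <- standardizeRecording(rec)
    expect_equal(samplingRate(out), 400)
    expect_equal(ncol(out@data) / 400, 4, tolerance = 0.01)
  }
})

test_that("envelope of an in-band tone is steady and matches the filter oracle", {
  fs <- 400
  t <- (0:(fs * 10 - 1)) / fs
  A <- 2
  tone <- A * sin(2 * pi * 100 * t)
  env <- highGammaEnvelope(neuralRecording(rbind(tone, -tone), fs))
  mid <- 300:700
  m <- mean(env@env[1, mid])
  expect_lt(sd(env@env[1, mid]) / m, 0.05)          # steady state
  # oracle: amplitude times the mean squared-magnitude response of the bank
  bands <- cocktailAAD:::highGammaBands()
  gains <- vapply(seq_len(nrow(bands)), function(i) {
    b <- cocktailAAD:::subBandFilter(bands[i, 1], bands[i, 2])
    fr <- signal::freqz(as.numeric(b), 1, n = 2048, Fs = fs)
    Mod(fr$h[which.min(abs(fr$f - 100))])^2
  }, 0)   # filtfilt applies the magnitude response twice
  expect_equal(m, A * mean(gains), tolerance = 0.05)
})

test_that("out-of-band energy is rejected and zero maps to zero", {
  fs <- 400
  t <- (0:(fs * 10 - 1)) / fs
  tone30 <- 2 * sin(2 * pi * 30 * t)
  tone100 <- 2 * sin(2 * pi * 100 * t)
  e30 <- highGammaEnvelope(neuralRecording(rbind(tone30, -tone30), fs))
  e100 <- highGammaEnvelope(neuralRecording(rbind(tone100, -tone100), fs))
  mid <- 300:700
  expect_lt(20 * log10(mean(e30@env[1, mid]) / mean(e100@env[1, mid])), -30)
  z <- highGammaEnvelope(neuralRecording(matrix(0, 2, 4000), fs))
  expect_true(all(z@env == 0))
})

test_that("envelope extraction is homogeneous and always lands at 100 Hz", {
  fs <- 400
  set.seed(2)
  x <- matrix(rnorm(2 * fs * 6), 2)
  e1 <- highGammaEnvelope(neuralRecording(x, fs))
  e3 <- highGammaEnvelope(neuralRecording(3 * x, fs))
  expect_equal(e3@env, 3 * e1@env, tolerance = 1e-6)
  expect_equal(samplingRate(e1), 100)
  expect_error(highGammaEnvelope(neuralRecording(x, 500)), "400 Hz")
  expect_error(highGammaEnvelope(neuralRecording(x[, 1:100], fs)),
               "transient")
})

test_that("t statistics match the textbook pooled-variance formula", {
  speech <- c(4.1, 5.2, 4.8, 5.5, 4.9)
  silence <- c(1.0, 1.4, 0.8, 1.2, 1.1)
  env <- new("HighGammaEnvelope",
             env = matrix(c(silence, speech), 1), fsHz = 100,
             bandEdges = cocktailAAD:::highGammaBands())
  # hand computation
  sp <- sqrt(((5 - 1) * var(speech) + (5 - 1) * var(silence)) / 8)
  tHand <- (mean(speech) - mean(silence)) / (sp * sqrt(2 / 5))
  tPkg <- unname(t.test(speech, silence, var.equal = TRUE)$statistic)
  expect_equal(tHand, tPkg, tolerance = 1e-12)
})

test_that("responsive electrodes are selected and null channels are not", {
  fs <- 100
  set.seed(3)
  onsets <- c(2, 8, 14, 20)
  n <- 26 * fs
  resp <- rnorm(n) * 0.1 + 1
  for (on in onsets) {
    idx <- round((on + 0.1) * fs):round((on + 1.6) * fs)
    resp[idx] <- resp[idx] + 1   # 10 SD elevation in the speech window
  }
  nullCh <- rnorm(n)
  env <- new("HighGammaEnvelope", env = rbind(resp, abs(nullCh)),
             fsHz = 100, bandEdges = cocktailAAD:::highGammaBands())
  sel <- selectSpeechResponsive(env, onsets, seed = 1L)
  expect_true(sel@selected[1])
  expect_false(sel@selected[2])
  # i.i.d. null channels essentially never clear t > 5
  hits <- 0
  for (s in 1:20) {
    envN <- new("HighGammaEnvelope",
                env = matrix(abs(rnorm(n)), 1), fsHz = 100,
                bandEdges = cocktailAAD:::highGammaBands())
    hits <- hits + sum(selectSpeechResponsive(envN, onsets,
                                              seed = s)@selected)
  }
  expect_identical(hits, 0)
  expect_error(selectSpeechResponsive(env, c(0.1), seed = 1L),
               "out of range")
})

test_that("selection draws are reproducible per seed", {
  fs <- 100
  set.seed(4)
  env <- new("HighGammaEnvelope", env = matrix(abs(rnorm(2 * 2600)), 2),
             fsHz = 100, bandEdges = cocktailAAD:::highGammaBands())
  s1 <- selectSpeechResponsive(env, c(2, 10), seed = 5L)
  s2 <- selectSpeechResponsive(env, c(2, 10), seed = 5L)
  expect_identical(s1@tStats, s2@tStats)
})
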