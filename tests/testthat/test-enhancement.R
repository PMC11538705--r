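# Enhancement gains, remixing, separation surrogate and signal metrics.

test_that("gain solution satisfies all three constraints in closed form", {
  g <- solveGains(9)
  expect_equal(g@k, 10^(-9 / 20), tolerance = 1e-12)
  expect_equal(g@k, 0.35481, tolerance = 1e-5)
  expect_equal(g@alphaAttended, 0.64519, tolerance = 1e-5)
  expect_identical(g@alphaUnattended, 0)
  expect_equal(g@k + g@alphaAttended, 1, tolerance = 1e-12)
  expect_equal(20 * log10((g@k + g@alphaAttended) /
                            (g@k + g@alphaUnattended)), 9,
               tolerance = 1e-9)
  # constraints hold to machine precision for arbitrary settings
  for (s in c(0, 3, 6, 12, 20)) {
    gs <- solveGains(s)
    expect_equal(gs@k + gs@alphaAttended, 1, tolerance = 1e-12)
    expect_equal(20 * log10(1 / gs@k), s, tolerance = 1e-9)
  }
  g0 <- solveGains(0)
  expect_equal(g0@k, 1)
  expect_equal(g0@alphaAttended, 0)   # identity limit: mixture unchanged
})

test_that("ideal remix hits the suppression target and conserves the attended stream", {
  sc <- fixtureScene()
  sep <- oracleSeparate(sc)        # ideal separation
  aud <- enhancementAudit(sc, sep, 1L, solveGains(9))
  expect_equal(aud$suppressionDb, 9, tolerance = 0.1)
  expect_lt(abs(aud$attendedPowerChangeDb), 0.01)
  out <- remixScene(sc, sep, 1L, solveGains(9))
  # attended component passes through exactly (correlation ~ 1)
  k <- solveGains(9)@k
  recon <- out@left - k * (sc@conv2@left + sc@noise@left)
  expect_gt(cor(recon, sc@conv1@left), 0.9999)
})

test_that("separation failure degrades the remix to an attenuated mixture", {
  sc <- fixtureScene()
  zero <- new("BinauralSignal", left = numeric(length(sc@mixture@left)),
              right = numeric(length(sc@mixture@right)),
              fsHz = sc@mixture@fsHz)
  sep <- new("SeparatedSources", streams = list(zero, zero),
             estTrajectories = list(sc@trajectories@trajA,
                                    sc@trajectories@trajB),
             fidelityMeta = list())
  expect_warning(out <- remixScene(sc, sep, 1L, solveGains(9)), "silent")
  expect_equal(out@left, solveGains(9)@k * sc@mixture@left)
})

test_that("the remix is linear in the scene", {
  sc <- fixtureScene()
  sep <- oracleSeparate(sc)
  out1 <- remixScene(sc, sep, 1L, solveGains(9))
  scScaled <- sc
  for (sl in c("mixture", "conv1", "conv2", "noise"))
    slot(scScaled, sl) <- cocktailAAD:::scaleBinaural(slot(sc, sl), 0.5)
  out2 <- remixScene(scScaled, oracleSeparate(scScaled), 1L, solveGains(9))
  expect_equal(out2@left, 0.5 * out1@left, tolerance = 1e-12)
})

test_that("snr follows the printed formula on algebraic cases", {
  set.seed(4)
  x <- rnorm(1000)
  expect_equal(snrDb(x, 0.5 * x), 10 * log10(1 / 0.25), tolerance = 1e-9)
  expect_equal(snrDb(x, 0.5 * x), 6.02, tolerance = 0.01)
  expect_equal(snrDb(x, -x), -6.02, tolerance = 0.01)
  expect_equal(snrDb(x, x), 120)   # capped identity
})

test_that("the oracle separator hits its SNR-improvement target", {
  sc <- fixtureScene()
  for (target in c(10, 15, 20)) {
    sep <- oracleSeparate(sc, targetSnriDb = target, seed = 3L)
    expect_equal(snrImprovementDb(sc, sep, 1L), target, tolerance = 0.5)
    expect_equal(snrImprovementDb(sc, sep, 2L), target, tolerance = 0.5)
  }
  ideal <- oracleSeparate(sc)
  expect_identical(ideal@streams[[1]]@left, sc@conv1@left)
  expect_equal(doaError(ideal@estTrajectories[[1]], sc@trajectories@trajA),
               0, tolerance = 0.5)   # grid snapping only
})

test_that("the oracle separator hits its DOA-noise target", {
  errs <- vapply(1:40, function(s) {
    sc <- fixtureScene()
    sep <- oracleSeparate(sc, targetSnriDb = 15, doaNoiseDeg = 4.2,
                          seed = s)
    (doaError(sep@estTrajectories[[1]], sc@trajectories@trajA) +
       doaError(sep@estTrajectories[[2]], sc@trajectories@trajB)) / 2
  }, 0)
  expect_equal(mean(errs), 4.2, tolerance = 0.42)
})

test_that("cross-domain features obey the printed definitions", {
  t <- (0:15999) / 16000
  tone <- sin(2 * pi * 500 * t)
  # identical channels
  same <- crossDomainFeatures(stftPair(new("BinauralSignal", left = tone,
                                           right = tone, fsHz = 16000)))
  expect_true(all(abs(same@sinIpd) < 1e-9))
  expect_true(all(abs(same@cosIpd - 1) < 1e-9))
  expect_true(all(abs(same@ild) < 1e-9))
  # magnitude scaling: Eq-form 10 log10 of the magnitude ratio
  g <- 0.5
  sp <- stftPair(new("BinauralSignal", left = tone, right = g * tone,
                     fsHz = 16000))
  cf <- crossDomainFeatures(sp)
  bin <- which.min(abs(sp@freqHz - 500))
  expect_equal(median(cf@ild[bin, ]), 10 * log10(1 / g), tolerance = 1e-6)
  # pure delay: IPD at the tone bin equals 2 pi f delta / fs
  delta <- 8
  del <- c(rep(0, delta), tone[1:(length(tone) - delta)])
  spd <- stftPair(new("BinauralSignal", left = tone, right = del,
                      fsHz = 16000))
  cfd <- crossDomainFeatures(spd)
  ipd <- atan2(cfd@sinIpd[bin, 200], cfd@cosIpd[bin, 200])
  expect_equal(ipd, 2 * pi * 500 * delta / 16000, tolerance = 0.02)
  # common scaling of both channels changes nothing at energetic bins
  sp2 <- stftPair(new("BinauralSignal", left = 3 * tone, right = 3 * del,
                      fsHz = 16000))
  cf2 <- crossDomainFeatures(sp2)
  expect_equal(cf2@ild[bin, ], cfd@ild[bin, ], tolerance = 1e-9)
  expect_equal(cf2@cosIpd[bin, ], cfd@cosIpd[bin, ], tolerance = 1e-6)
})

test_that("DOA error handles exact, offset and mismatched supports", {
  tr <- constTrajectory(10, n = 100, rateHz = 12.5)
  expect_equal(doaError(tr, tr), 0)
  off <- constTrajectory(20, n = 100, rateHz = 12.5)
  expect_equal(doaError(off, tr), 10)
})

test_that("receptive-field arithmetic reproduces the architecture numbers", {
  expect_equal(receptiveFieldSeconds(separatorArchSpec()), 2.542)
  tiny <- separatorArchSpec(nStacks = 1, blocksPerStack = 1,
                            kernelSize = 3, dilationBase = 1)
  expect_equal(receptiveFieldSeconds(tiny), 3 * 0.002)
  # doubling the stacks nearly doubles the receptive field
  d1 <- receptiveFieldSeconds(separatorArchSpec(nStacks = 5))
  d2 <- receptiveFieldSeconds(separatorArchSpec(nStacks = 10))
  expect_equal(d2 - 0.002, 2 * (d1 - 0.002), tolerance = 1e-12)
})
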