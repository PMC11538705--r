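# CCA attention decoder: lag embedding, the CCA core against independent
# oracles, windowed voting, CPI, behavior correction and transition times.

test_that("lag embedding matches the worked example and shape contract", {
  X <- matrix(1:4, 1)
  L <- lagEmbed(X, 2)
  expect_equal(L, cbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(lagEmbed(X, 1), t(X))
  X2 <- matrix(rnorm(3 * 30), 3)
  expect_equal(dim(lagEmbed(X2, 5)), c(26, 15))
})

test_that("the CCA core agrees with a generalized-eigenvalue oracle", {
  set.seed(7)
  n <- 400
  X <- matrix(rnorm(n * 2), n)
  Y <- X %*% matrix(c(1, 0.3, -0.2, 0.8), 2) + 0.5 * matrix(rnorm(n * 2), n)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Cxx <- crossprod(Xc) / (n - 1); Cyy <- crossprod(Yc) / (n - 1)
  Cxy <- crossprod(Xc, Yc) / (n - 1)
  cc <- cocktailAAD:::ccaFromCov(Cxx, Cyy, Cxy, ridge = 0)
  expect_equal(cc$cors, ccaEigenOracle(X, Y), tolerance = 1e-8)
  # and with base R's cancor as a second, independent reference
  expect_equal(cc$cors, cancor(X, Y)$cor, tolerance = 1e-8)
})

test_that("streaming PCA matches prcomp on stacked data", {
  set.seed(8)
  A <- matrix(rnorm(200 * 6), 200)
  B <- matrix(rnorm(150 * 6), 150)
  acc <- cocktailAAD:::covAccumInit(6)
  acc <- cocktailAAD:::covAccumAdd(acc, A)
  acc <- cocktailAAD:::covAccumAdd(acc, B)
  p <- cocktailAAD:::pcaFromCov(cocktailAAD:::covAccumFinish(acc),
                                retain = 0.95)
  ref <- prcomp(rbind(A, B))
  expect_equal(p$mean, unname(ref$center), tolerance = 1e-10)
  vr <- cumsum(ref$sdev^2) / sum(ref$sdev^2)
  expect_identical(p$k, as.integer(which(vr >= 0.95)[1]))
  # spans agree up to sign
  for (j in seq_len(p$k))
    expect_equal(abs(sum(p$rotation[, j] * ref$rotation[, j])), 1,
                 tolerance = 1e-6)
})

test_that("canonical correlations are invariant to affine feature scaling", {
  exp <- fixtureNoiselessExp()
  labs <- lapply(exp$trials, function(t) cuedLabels(t$durationS))
  m1 <- fitCCA(lapply(exp$trials[1:2], `[[`, "env"),
               lapply(exp$trials[1:2], `[[`, "feats1"),
               lapply(exp$trials[1:2], `[[`, "feats2"), labs[1:2])
  rescale <- function(f) initialize(f, mel = 3 * f@mel + 2,
                                    traj = 0.5 * f@traj - 7)
  m2 <- fitCCA(lapply(exp$trials[1:2], `[[`, "env"),
               lapply(exp$trials[1:2], function(t) rescale(t$feats1)),
               lapply(exp$trials[1:2], function(t) rescale(t$feats2)),
               labs[1:2])
  expect_equal(m1@canCors[1:3], m2@canCors[1:3], tolerance = 1e-6)
})

test_that("PCA blocks retain at least 95% variance", {
  exp <- fixtureNoiselessExp()
  res <- lotoDecode(exp, windowSizesS = 4, labelPolicy = "cued",
                    heldOut = 1L)
  m <- res$models[[1]]
  expect_gte(m@pcaNeural$varFrac, 0.95)
  expect_gte(m@pcaMel$varFrac, 0.95)
  expect_gte(m@pcaTraj$varFrac, 0.95)
  expect_true(all(diff(m@canCors) <= 1e-8))
})

test_that("time-shuffled neural training destroys held-out correlations", {
  exp <- fixtureNoiselessExp()
  labs <- lapply(exp$trials, function(t) cuedLabels(t$durationS))
  shuf <- lapply(exp$trials[1:2], function(t) {
    set.seed(1)
    initialize(t$env, env = t$env@env[, sample(ncol(t$env@env))])
  })
  mS <- fitCCA(shuf,
               lapply(exp$trials[1:2], `[[`, "feats1"),
               lapply(exp$trials[1:2], `[[`, "feats2"), labs[1:2])
  mA <- fitCCA(lapply(exp$trials[1:2], `[[`, "env"),
               lapply(exp$trials[1:2], `[[`, "feats1"),
               lapply(exp$trials[1:2], `[[`, "feats2"), labs[1:2])
  ho <- exp$trials[[3]]
  set.seed(2)
  hoShuf <- initialize(ho$env, env = ho$env@env[, sample(ncol(ho$env@env))])
  corHo <- function(m, env) {
    pr <- cocktailAAD:::projectTrial(m, env, list(ho$feats1, ho$feats2))
    abs(cor(pr$U[, 1], pr$V[[1]][, 1]))
  }
  # temporal alignment destroyed: held-out correlation collapses
  expect_lt(corHo(mS, hoShuf), 0.2)
  expect_gt(corHo(mA, ho$env), 0.8)
})

test_that("vote counts map to CPI per the index definition", {
  exp <- fixtureNoiselessExp()
  res <- lotoDecode(exp, windowSizesS = 2, labelPolicy = "cued",
                    heldOut = 1L)
  w <- decodingWindows(res$results[[1]][[1]])
  expect_true(all(w$cpi == w$votes_for_1 / 3 - 0.5))
  expect_true(all(w$cpi[w$votes_for_1 == 3] == 0.5))
  expect_true(all(w$winner[w$votes_for_1 >= 2] == 1L))
  # the index attains +1/6 at two of three votes
  expect_equal(unique(w$cpi[w$votes_for_1 == 2]),
               if (any(w$votes_for_1 == 2)) 1 / 6 else numeric())
})

test_that("identical candidate streams fall to the stream-1 tie-break", {
  exp <- fixtureNoiselessExp()
  res <- lotoDecode(exp, windowSizesS = 4, labelPolicy = "cued",
                    heldOut = 1L)
  m <- res$models[[1]]
  ho <- exp$trials[[1]]
  dr <- decodeWindows(m, ho$env, list(ho$feats1, ho$feats1), 4)
  w <- decodingWindows(dr)
  expect_true(all(w$winner == 1L))
  expect_true(all(w$degenerate))
})

test_that("leave-one-trial-out folds never see the held-out trial", {
  exp <- fixtureNoiselessExp()
  res1 <- lotoDecode(exp, windowSizesS = 4, labelPolicy = "cued",
                     heldOut = 3L)
  exp2 <- exp
  set.seed(99)
  exp2$trials[[3]]$env <- initialize(exp$trials[[3]]$env,
                                     env = matrix(abs(rnorm(length(
                                       exp$trials[[3]]$env@env))),
                                       nrow(exp$trials[[3]]$env@env)))
  res2 <- lotoDecode(exp2, windowSizesS = 4, labelPolicy = "cued",
                     heldOut = 3L)
  m1 <- res1$models[[1]]; m2 <- res2$models[[1]]
  expect_identical(m1@wNeural, m2@wNeural)
  expect_identical(m1@normalizer, m2@normalizer)
  expect_identical(m1@canCors, m2@canCors)
})

test_that("behavior correction swaps exactly the press-bounded portion", {
  labs <- cuedLabels(40)
  ev <- data.frame(onset_s = c(6, 13, 20, 27, 34),
                   stream = c(1L, 2L, 2L, 1L, 1L))
  # two uncued detections at 13.5 and 20.5 -> swap on [13.5, 20.5]
  pr <- new("ButtonPresses", pressTimesS = c(13.5, 20.5))
  cor1 <- applyBehaviorCorrection(labs, pr, ev)
  expect_true(cor1$swapped)
  expect_equal(cor1$interval_s, c(13.5, 20.5))
  tt <- (seq_along(cor1$labels@attendedStream) - 1) / 100
  expect_true(all(cor1$labels@attendedStream[tt >= 13.5 & tt <= 20.5] == 2L))
  expect_true(all(cor1$labels@attendedStream[tt < 13.5 | tt > 20.5] == 1L))
  # a single uncued detection leaves labels unchanged
  pr1 <- new("ButtonPresses", pressTimesS = 13.5)
  cor2 <- applyBehaviorCorrection(labs, pr1, ev)
  expect_false(cor2$swapped)
  expect_identical(cor2$labels@attendedStream, labs@attendedStream)
  # no presses at all: unchanged
  cor3 <- applyBehaviorCorrection(labs, new("ButtonPresses",
                                            pressTimesS = numeric()), ev)
  expect_false(cor3$swapped)
})

test_that("transition time follows the step-response oracle", {
  centers <- seq(2, 38, by = 4)
  cpi <- ifelse(centers < 20, 0.5, -0.5)
  tt <- transitionTime(cpi, centers, 20)
  expect_lte(tt, 4)              # within one window length of the swap
  expect_gte(tt, 0)
  # never crossing: undefined
  expect_true(is.na(transitionTime(rep(0.5, 10), centers[1:10], 20)))
  # invariance to stream relabeling (CPI sign flip)
  expect_equal(transitionTime(-cpi, centers, 20), tt)
  # exact linear interpolation between centers
  cpi2 <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.25, -0.25, -0.5, -0.5, -0.5)
  tt2 <- transitionTime(cpi2, centers, 20)
  expect_equal(tt2, (22 + 4 * 0.5) - 20)  # zero halfway between 22 and 26
})

test_that("sliding CPI tracks a mid-trial attention switch", {
  exp <- fixtureNoiselessExp()
  labs <- lapply(exp$trials, function(t) cuedLabels(t$durationS))
  m <- fitCCA(lapply(exp$trials[1:2], `[[`, "env"),
              lapply(exp$trials[1:2], `[[`, "feats1"),
              lapply(exp$trials[1:2], `[[`, "feats2"), labs[1:2])
  ho <- exp$trials[[3]]
  # swapping the candidate order flips the CPI sign
  sl1 <- slidingCpi(m, ho$env, list(ho$feats1, ho$feats2))
  sl2 <- slidingCpi(m, ho$env, list(ho$feats2, ho$feats1))
  expect_gt(mean(sl1$cpi), 0.3)
  expect_lt(mean(sl2$cpi), -0.3)
})
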