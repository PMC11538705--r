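# CCA core: covariance-accumulated PCA (95% variance) on lag-embedded
# blocks and canonical correlation via the whitened cross-covariance SVD
# with a small ridge on the covariance diagonals.

# Accumulator for streaming covariance over trials: n, column sums, X'X.
covAccumInit <- function(p) list(n = 0, s = numeric(p), ss = matrix(0, p, p))

covAccumAdd <- function(acc, X) {
  acc$n <- acc$n + nrow(X)
  acc$s <- acc$s + colSums(X)
  acc$ss <- acc$ss + crossprod(X)
  acc
}

covAccumFinish <- function(acc) {
  mu <- acc$s / acc$n
  C <- (acc$ss - acc$n * tcrossprod(mu)) / (acc$n - 1)
  list(mean = mu, cov = (C + t(C)) / 2, n = acc$n)
}

# PCA retaining >= `retain` of the variance, from a covariance matrix.
pcaFromCov <- function(mc, retain = 0.95) {
  e <- eigen(mc$cov, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  frac <- cumsum(vals) / sum(vals)
  k <- which(frac >= retain)[1]
  if (is.na(k)) k <- length(vals)
  list(mean = mc$mean, rotation = e$vectors[, seq_len(k), drop = FALSE],
       varFrac = frac[k], k = k)
}

pcaApply <- function(X, p) sweep(X, 2, p$mean) %*% p$rotation

# Inverse square root of a symmetric PSD matrix with a ridge.
invSqrtm <- function(C, ridge = 1e-8) {
  C <- C + diag(ridge * mean(diag(C)) + ridge, nrow(C))
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, max(e$values) * 1e-12)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

# CCA from the joint covariance of two projected views.
ccaFromCov <- function(Cxx, Cyy, Cxy, ridge = 1e-8) {
  Wxh <- invSqrtm(Cxx, ridge)
  Wyh <- invSqrtm(Cyy, ridge)
  sv <- svd(Wxh %*% Cxy %*% Wyh)
  list(wx = Wxh %*% sv$u, wy = Wyh %*% sv$v,
       cors = pmin(pmax(sv$d, 0), 1))
}

#' Canonical correlations by a brute-force generalized-eigenvalue solve
#'
#' Independent reference for the CCA core on small instances: the squared
#' canonical correlations are the eigenvalues of
#' Cxx^-1 Cxy Cyy^-1 Cyx.
#'
#' @param X,Y observation x feature matrices.
#' @return canonical correlations, descending.
#' @export
ccaEigenOracle <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  n <- nrow(X)
  Cxx <- crossprod(Xc) / (n - 1); Cyy <- crossprod(Yc) / (n - 1)
  Cxy <- crossprod(Xc, Yc) / (n - 1)
  M <- solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy))
  ev <- sort(Re(eigen(M)$values), decreasing = TRUE)
  sqrt(pmin(pmax(ev[seq_len(min(ncol(X), ncol(Y)))], 0), 1))
}

# Lag-embedded blocks of one trial: neural, mel and trajectory, truncated
# to the common start-aligned row count.
lagBlocksTrial <- function(env, feats, neuralLags, stimLags) {
  nF <- min(ncol(env@env), ncol(feats@mel))
  Xn <- lagEmbed(env@env[, seq_len(nF), drop = FALSE], neuralLags)
  Xm <- lagEmbed(feats@mel[, seq_len(nF), drop = FALSE], stimLags)
  Xt <- lagEmbed(feats@traj[, seq_len(nF), drop = FALSE], stimLags)
  nr <- min(nrow(Xn), nrow(Xm))
  list(neural = Xn[seq_len(nr), , drop = FALSE],
       mel = Xm[seq_len(nr), , drop = FALSE],
       traj = Xt[seq_len(nr), , drop = FALSE])
}

#' Fit the trajectory-augmented CCA attention decoder
#'
#' Training pipeline: (i) pooled feature normalization is fit on the
#' training trials only and applied everywhere; (ii) attended stimulus
#' features are composed frame-wise from the per-stream features according
#' to the (possibly behavior-corrected) attention labels; (iii) neural
#' envelopes and stimulus features are start-aligned lag-embedded (500 ms
#' neural, 200 ms stimulus receptive fields at 100 Hz); (iv) PCA retaining
#' at least 95% of the variance is applied per block (neural, mel,
#' trajectory); (v) CCA pairs the neural block with the concatenated
#' stimulus blocks.
#'
#' @param envList list of [HighGammaEnvelope-class], one per training trial.
#' @param featsList1,featsList2 per-trial [StimFeatures-class] for streams
#'   1 and 2 (unnormalized).
#' @param labelsList per-trial [AttentionLabels-class] giving the attended
#'   stream over time (training labels).
#' @param useTrajectory fuse trajectory features (default TRUE).
#' @param neuralLags,stimLags receptive fields in frames (50, 20).
#' @param retain PCA variance fraction (0.95).
#' @param ridge covariance ridge for the CCA solve (1e-8).
#' @return a [CCAModel-class].
#' @export
fitCCA <- function(envList, featsList1, featsList2, labelsList,
                   useTrajectory = TRUE, neuralLags = 50L, stimLags = 20L,
                   retain = 0.95, ridge = 1e-8) {
  stopifnot(length(envList) >= 2)
  nrm <- fitFeatureNormalizer(c(featsList1, featsList2))
  attended <- lapply(seq_along(envList), function(i) {
    f1 <- applyFeatureNormalizer(featsList1[[i]], nrm)
    f2 <- applyFeatureNormalizer(featsList2[[i]], nrm)
    composeAttendedFeatures(f1, f2, labelsList[[i]])
  })
  # pass 1: per-block covariance accumulation for PCA
  accN <- accM <- accT <- NULL
  for (i in seq_along(envList)) {
    b <- lagBlocksTrial(envList[[i]], attended[[i]], neuralLags, stimLags)
    if (is.null(accN)) {
      accN <- covAccumInit(ncol(b$neural))
      accM <- covAccumInit(ncol(b$mel))
      accT <- covAccumInit(ncol(b$traj))
    }
    accN <- covAccumAdd(accN, b$neural)
    accM <- covAccumAdd(accM, b$mel)
    accT <- covAccumAdd(accT, b$traj)
  }
  pN <- pcaFromCov(covAccumFinish(accN), retain)
  pM <- pcaFromCov(covAccumFinish(accM), retain)
  pT <- pcaFromCov(covAccumFinish(accT), retain)
  # pass 2: covariance of the projected views for the CCA solve
  accJ <- NULL
  for (i in seq_along(envList)) {
    b <- lagBlocksTrial(envList[[i]], attended[[i]], neuralLags, stimLags)
    U <- pcaApply(b$neural, pN)
    V <- if (useTrajectory) cbind(pcaApply(b$mel, pM), pcaApply(b$traj, pT))
         else pcaApply(b$mel, pM)
    J <- cbind(U, V)
    if (is.null(accJ)) accJ <- covAccumInit(ncol(J))
    accJ <- covAccumAdd(accJ, J)
  }
  mc <- covAccumFinish(accJ)
  kU <- pN$k
  Cxx <- mc$cov[seq_len(kU), seq_len(kU), drop = FALSE]
  Cyy <- mc$cov[-seq_len(kU), -seq_len(kU), drop = FALSE]
  Cxy <- mc$cov[seq_len(kU), -seq_len(kU), drop = FALSE]
  cc <- ccaFromCov(Cxx, Cyy, Cxy, ridge)
  if (length(cc$cors) < 3)
    warning("fewer than 3 canonical components available after PCA")
  new("CCAModel", neuralLags = as.integer(neuralLags),
      stimLags = as.integer(stimLags), normalizer = nrm,
      pcaNeural = pN, pcaMel = pM, pcaTraj = pT,
      wNeural = cc$wx, wStim = cc$wy, canCors = cc$cors,
      nVoteComponents = 3L, useTrajectory = useTrajectory,
      meta = list(nTrainTrials = length(envList), nFrames = accJ$n))
}

#' Compose attended stimulus features from labels
#'
#' Frame-wise selection between the two streams' features according to the
#' attended-stream label timeline.
#'
#' @param feats1,feats2 [StimFeatures-class] (same normalization state).
#' @param labels an [AttentionLabels-class] at the feature rate.
#' @return a [StimFeatures-class].
#' @export
composeAttendedFeatures <- function(feats1, feats2, labels) {
  nF <- min(ncol(feats1@mel), ncol(feats2@mel))
  lab <- rep(labels@attendedStream, length.out = nF)
  mel <- feats1@mel[, seq_len(nF), drop = FALSE]
  tr <- feats1@traj[, seq_len(nF), drop = FALSE]
  sel <- lab == 2L
  mel[, sel] <- feats2@mel[, seq_len(nF), drop = FALSE][, sel]
  tr[, sel] <- feats2@traj[, seq_len(nF), drop = FALSE][, sel]
  initialize(feats1, mel = mel, traj = tr)
}

# Project a trial into canonical space. Returns row-aligned U (neural) and
# one V per candidate stream, plus the row start times in seconds.
projectTrial <- function(model, env, featsList) {
  featsList <- lapply(featsList, applyFeatureNormalizer,
                      nrm = model@normalizer)
  out <- vector("list", length(featsList))
  U <- NULL
  for (s in seq_along(featsList)) {
    b <- lagBlocksTrial(env, featsList[[s]], model@neuralLags,
                        model@stimLags)
    if (is.null(U)) U <- pcaApply(b$neural, model@pcaNeural) %*% model@wNeural
    V <- if (model@useTrajectory)
      cbind(pcaApply(b$mel, model@pcaMel), pcaApply(b$traj, model@pcaTraj))
    else pcaApply(b$mel, model@pcaMel)
    out[[s]] <- V %*% model@wStim
  }
  list(U = U, V = out, startS = (seq_len(nrow(U)) - 1) / 100)
}
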