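# Synthetic neural data with the statistical structure the decoder
# assumes: high-gamma envelopes that linearly track the attended stream's
# spectrogram and trajectory over 0-500 ms lags, a weaker unattended
# contribution, additive noise and occasional attention lapses.

#' Construct a linear forward model
#'
#' Kernels are Gaussian random fields smoothed along the lag axis
#' (temporal smoothness ~50 ms), mimicking smooth evoked responses so that
#' CCA filters are estimable from tens of trials.
#'
#' @param nChannels synthetic electrode count (default 30, comparable to
#'   per-subject speech-responsive counts).
#' @param nMel mel-feature rows the kernels act on (default 40: 20 bins x
#'   two ears).
#' @param nLags kernel lag span in 100 Hz frames (default 50 = 500 ms).
#' @param unattendedGain relative gain of the unattended stream's
#'   contribution, in \[0, 1) (default 0.3).
#' @param noiseSd additive noise SD relative to the SD of the noiseless
#'   signal component (1 = 0 dB feature SNR; 0 = noiseless).
#' @param trajGain relative strength of the trajectory kernels versus the
#'   spectrogram kernels (default 1).
#' @param smoothLagS kernel smoothness along lags in seconds (0.05).
#' @param seed integer seed.
#' @return a [ForwardModel-class].
#' @export
forwardModel <- function(nChannels = 30L, nMel = 40L, nLags = 50L,
                         unattendedGain = 0.3, noiseSd = 20,
                         trajGain = 1, smoothLagS = 0.05, seed = 1L) {
  set.seed(seed)
  smoothLag <- function(v) {
    sdF <- smoothLagS * 100
    half <- ceiling(3 * sdF)
    k <- dnorm(-half:half, sd = sdF); k <- k / sum(k)
    vp <- c(rev(v[seq_len(half)]), v, rev(v)[seq_len(half)])
    as.numeric(stats::filter(vp, k, sides = 2))[half + seq_along(v)]
  }
  K <- array(rnorm(nChannels * nMel * nLags), c(nChannels, nMel, nLags))
  for (c in seq_len(nChannels)) for (f in seq_len(nMel))
    K[c, f, ] <- smoothLag(K[c, f, ])
  Kt <- t(vapply(seq_len(nChannels),
                 function(c) smoothLag(rnorm(nLags)), numeric(nLags)))
  K <- K / sqrt(mean(K^2))
  Kt <- Kt / sqrt(mean(Kt^2)) * trajGain
  new("ForwardModel", spectroKernels = K, trajKernels = Kt,
      unattendedGain = unattendedGain, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' Simulate an attention-label timeline with lapses
#'
#' Attention defaults to the cued stream; lapses toward the uncued stream
#' start as a Poisson process (while attending) and last exponentially
#' distributed durations.
#'
#' @param trialDurationS trial duration in seconds.
#' @param lapseRatePerMin lapse onset rate per attended minute (default 0).
#' @param meanLapseS mean lapse duration in seconds (default 8).
#' @param seed integer seed.
#' @param rateHz label rate (100).
#' @return an [AttentionLabels-class].
#' @export
simulateAttention <- function(trialDurationS, lapseRatePerMin = 0,
                              meanLapseS = 8, seed = 1L, rateHz = 100) {
  stopifnot(lapseRatePerMin >= 0, meanLapseS >= 0)
  set.seed(seed)
  n <- round(trialDurationS * rateHz)
  lab <- rep(1L, n)
  ivals <- NULL
  if (lapseRatePerMin > 0 && meanLapseS > 0) {
    rate <- lapseRatePerMin / 60
    t <- 0
    repeat {
      t <- t + rexp(1, rate)
      if (t >= trialDurationS) break
      len <- rexp(1, 1 / meanLapseS)
      t1 <- min(t + len, trialDurationS)
      i0 <- max(1, round(t * rateHz)); i1 <- max(1, round(t1 * rateHz))
      lab[i0:i1] <- 2L
      ivals <- rbind(ivals, c(t, t1))
      t <- t1
    }
  }
  new("AttentionLabels", attendedStream = lab,
      lapseIntervals = if (is.null(ivals)) matrix(numeric(), 0, 2) else ivals,
      rateHz = rateHz)
}

# Convolve features with kernels: env[c, t] = sum_f sum_d K[c,f,d+1] X[f,t-d]
# (zero-padded start), via a lag-embedded matrix product.
convolveKernels <- function(X, K) {
  nLags <- dim(K)[3]
  Xp <- cbind(matrix(0, nrow(X), nLags - 1), X)
  L <- lagEmbed(Xp, nLags)       # rows t: [X[,t-L+1] ... X[,t]]
  # column block j holds delay d = nLags - j
  W <- matrix(0, ncol(L), dim(K)[1])
  nF <- nrow(X)
  for (j in seq_len(nLags)) {
    d <- nLags - j
    W[(j - 1) * nF + seq_len(nF), ] <- t(K[, , d + 1, drop = TRUE])
  }
  t(L %*% W)
}

#' Simulate high-gamma envelopes for a trial scene
#'
#' env = kernels (*) attended features + unattendedGain * (kernels (*)
#' unattended features) + noise, shifted nonnegative and rectified at 0.
#' Features are the scene's clean per-stream mel spectrograms and
#' trajectories, standardized per trial for generator scaling.
#'
#' @param scene a [TrialScene-class] (or a list with precomputed
#'   `feats1`, `feats2` [StimFeatures-class]).
#' @param labels an [AttentionLabels-class] for the trial.
#' @param fm a [ForwardModel-class].
#' @param seed integer seed for the noise draw.
#' @return a [HighGammaEnvelope-class] at 100 Hz.
#' @export
simulateNeural <- function(scene, labels, fm, seed = fm@seed) {
  if (is(scene, "TrialScene")) {
    f1 <- computeStimFeatures(scene@conv1, scene@trajectories@trajA, 1L)
    f2 <- computeStimFeatures(scene@conv2, scene@trajectories@trajB, 2L)
  } else {
    f1 <- scene$feats1; f2 <- scene$feats2
  }
  std <- function(f) {
    mel <- (f@mel - rowMeans(f@mel)) / pmax(apply(f@mel, 1, sd), 1e-9)
    tr <- (f@traj - mean(f@traj)) / max(sd(as.numeric(f@traj)), 1e-9)
    initialize(f, mel = mel, traj = tr)
  }
  f1 <- std(f1); f2 <- std(f2)
  att <- composeAttendedFeatures(f1, f2, labels)
  una <- composeAttendedFeatures(f2, f1, labels)
  if (nrow(att@mel) != dim(fm@spectroKernels)[2])
    stop("feature/kernel dimension mismatch")
  sig <- convolveKernels(att@mel, fm@spectroKernels) +
    convolveKernels(att@traj,
                    array(fm@trajKernels,
                          c(nrow(fm@trajKernels), 1, ncol(fm@trajKernels))))
  ung <- fm@unattendedGain
  if (ung > 0)
    sig <- sig + ung * (convolveKernels(una@mel, fm@spectroKernels) +
                          convolveKernels(una@traj,
                                          array(fm@trajKernels,
                                                c(nrow(fm@trajKernels), 1,
                                                  ncol(fm@trajKernels)))))
  set.seed(seed)
  noise <- fm@noiseSd * sd(as.numeric(sig)) *
    matrix(rnorm(length(sig)), nrow(sig))
  env <- sig + noise
  env <- env - min(env)          # affine shift keeps the map linear
  env[env < 0] <- 0
  new("HighGammaEnvelope", env = env, fsHz = 100,
      bandEdges = highGammaBands())
}

#' Broadband carrier emission for end-to-end preprocessing tests
#'
#' Emits 400 Hz multichannel data whose 70-150 Hz content is a bank of
#' tones (one per high-gamma sub-band, random phases) amplitude-modulated
#' by the given envelopes, so that [highGammaEnvelope()] recovers the
#' intended envelopes up to a constant gain.
#'
#' @param env a [HighGammaEnvelope-class].
#' @param seed integer seed (tone phases).
#' @return a [NeuralRecording-class] at 400 Hz.
#' @export
broadbandFromEnvelope <- function(env, seed = 1L) {
  set.seed(seed)
  fs <- 400
  n100 <- ncol(env@env)
  n <- n100 * 4
  bands <- highGammaBands()
  fc <- rowMeans(bands)
  tUp <- (seq_len(n) - 1) / fs
  t100 <- (seq_len(n100) - 1) / 100
  out <- matrix(0, nrow(env@env), n)
  for (ch in seq_len(nrow(env@env))) {
    carrier <- rowSums(sin(outer(tUp, 2 * pi * fc) +
                             rep(runif(length(fc), 0, 2 * pi),
                                 each = n)))
    e <- interpSeries(t100, env@env[ch, ], tUp)
    out[ch, ] <- carrier / length(fc) * e
  }
  neuralRecording(out, fs)
}

#' Simulate button presses for the 1-back task
#'
#' For each repeat in the stream attended at its onset the subject presses
#' with probability `pHit` after a truncated-normal reaction time; repeats
#' in the other stream elicit presses with probability `pFa`.
#'
#' @param labels an [AttentionLabels-class].
#' @param events repeat-event table (`onset_s`, `stream`).
#' @param pHit,pFa response probabilities.
#' @param rtMeanS,rtSdS reaction-time mean and SD in seconds; must satisfy
#'   rtMeanS + 2 rtSdS < 2 so simulated hits are scoreable.
#' @param seed integer seed.
#' @return a [ButtonPresses-class].
#' @export
simulateButtonPresses <- function(labels, events, pHit = 0.85, pFa = 0.1,
                                  rtMeanS = 0.9, rtSdS = 0.25, seed = 1L) {
  stopifnot(pHit >= 0, pHit <= 1, pFa >= 0, pFa <= 1,
            rtMeanS + 2 * rtSdS < 2)
  set.seed(seed)
  rt <- function() {
    repeat {
      r <- rnorm(1, rtMeanS, rtSdS)
      if (r > 0.15 && r < 1.99) return(r)
    }
  }
  times <- numeric(0)
  lab <- labels@attendedStream
  for (i in seq_len(nrow(events))) {
    li <- min(length(lab), max(1L, round(events$onset_s[i] *
                                           labels@rateHz) + 1L))
    p <- if (events$stream[i] == lab[li]) pHit else pFa
    if (runif(1) < p) times <- c(times, events$onset_s[i] + rt())
  }
  times <- sort(times)
  if (length(times) > 1)
    times[c(FALSE, diff(times) <= 0)] <-
      times[c(FALSE, diff(times) <= 0)] + 1e-4
  new("ButtonPresses", pressTimesS = sort(times))
}
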