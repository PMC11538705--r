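# Experiment harness: simulate a full synthetic study (scenes + neural +
# behavior) and evaluate the decoder with leave-one-trial-out folds.

#' Simulate a synthetic AAD experiment
#'
#' For each trial: builds an acoustic scene, computes per-stream stimulus
#' features, simulates an attention-label timeline (with optional lapses),
#' synthetic high-gamma envelopes from the linear forward model, and
#' button presses for the 1-back task. Audio waveforms are dropped after
#' feature extraction to keep the experiment object small.
#'
#' @param nTrials number of trials.
#' @param fm a [ForwardModel-class] shared across trials.
#' @param durationS fixed trial duration, or NULL to draw from the trial
#'   statistics (Normal(44.2, 2) truncated to \[40, 50\]).
#' @param lapseRatePerMin,meanLapseS attention-lapse parameters.
#' @param pHit,pFa,rtMeanS,rtSdS behavioral parameters.
#' @param noiseLevelDb scene noise level (-9 or -12; alternates if NULL).
#' @param seed integer seed.
#' @return list of per-trial records (`feats1`, `feats2`, `labels`, `env`,
#'   `events`, `presses`, `durationS`, `scripts`) plus `fm` and `seed`.
#' @export
simulateExperiment <- function(nTrials, fm = forwardModel(),
                               durationS = NULL, lapseRatePerMin = 0,
                               meanLapseS = 8, pHit = 0.85, pFa = 0.05,
                               rtMeanS = 0.9, rtSdS = 0.25,
                               noiseLevelDb = NULL, seed = 1L) {
  trials <- vector("list", nTrials)
  for (i in seq_len(nTrials)) {
    si <- seed * 1000L + i
    lev <- if (is.null(noiseLevelDb)) c(-9, -12)[(i %% 2) + 1] else noiseLevelDb
    scene <- buildTrialScene(seed = si, durationS = durationS,
                             noiseLevelDb = lev)
    f1 <- computeStimFeatures(scene@conv1, scene@trajectories@trajA, 1L)
    f2 <- computeStimFeatures(scene@conv2, scene@trajectories@trajB, 2L)
    labels <- simulateAttention(durationS(scene@mixture),
                                lapseRatePerMin = lapseRatePerMin,
                                meanLapseS = meanLapseS, seed = si + 1L)
    env <- simulateNeural(list(feats1 = f1, feats2 = f2), labels, fm,
                          seed = si + 2L)
    ev <- repeatEvents(scene)
    presses <- simulateButtonPresses(labels, ev, pHit = pHit, pFa = pFa,
                                     rtMeanS = rtMeanS, rtSdS = rtSdS,
                                     seed = si + 3L)
    trials[[i]] <- list(feats1 = f1, feats2 = f2, labels = labels,
                        env = env, events = ev, presses = presses,
                        durationS = durationS(scene@mixture),
                        scripts = scene@scripts)
  }
  list(trials = trials, fm = fm, seed = seed)
}

# Labels used for training/evaluation under a labeling policy:
# "corrected" starts from the cued assumption and swaps portions flagged by
# the behavioral correction; "cued" assumes the cued stream throughout;
# "true" uses the hidden simulated attention timeline.
experimentLabels <- function(exp, policy = c("corrected", "cued", "true")) {
  policy <- match.arg(policy)
  lapply(exp$trials, function(tr) {
    base <- cuedLabels(tr$durationS)
    switch(policy,
           cued = base,
           true = tr$labels,
           corrected = applyBehaviorCorrection(base, tr$presses,
                                               tr$events)$labels)
  })
}

#' Leave-one-trial-out decoding evaluation
#'
#' For each fold, fits the CCA decoder on all other trials (pooled feature
#' normalization, attended-feature composition per the labeling policy,
#' PCA, CCA) and decodes the held-out trial at each window size. The
#' held-out trial contributes nothing to normalization, PCA or CCA.
#'
#' @param exp output of [simulateExperiment()].
#' @param windowSizesS window sizes in seconds.
#' @param useTrajectory fuse trajectory features (default TRUE).
#' @param labelPolicy "corrected" (behavior-corrected, the default),
#'   "cued" (assume the cued stream throughout) or "true" (the hidden
#'   simulated labels).
#' @param heldOut optional subset of trials to hold out (default: all).
#' @return list: `accuracy` (trials x window sizes matrix), `results`
#'   (nested [DecodingResult-class] objects), `models`.
#' @export
lotoDecode <- function(exp, windowSizesS = c(0.5, 1, 2, 4, 8, 16, 32),
                       useTrajectory = TRUE,
                       labelPolicy = "corrected", heldOut = NULL) {
  n <- length(exp$trials)
  if (is.null(heldOut)) heldOut <- seq_len(n)
  labs <- experimentLabels(exp, labelPolicy)
  acc <- matrix(NA_real_, length(heldOut), length(windowSizesS),
                dimnames = list(paste0("trial", heldOut),
                                paste0("win", windowSizesS)))
  results <- vector("list", length(heldOut))
  models <- vector("list", length(heldOut))
  for (j in seq_along(heldOut)) {
    ho <- heldOut[j]
    tr <- setdiff(seq_len(n), ho)
    model <- fitCCA(lapply(exp$trials[tr], `[[`, "env"),
                    lapply(exp$trials[tr], `[[`, "feats1"),
                    lapply(exp$trials[tr], `[[`, "feats2"),
                    labs[tr], useTrajectory = useTrajectory)
    models[[j]] <- model
    results[[j]] <- lapply(seq_along(windowSizesS), function(k) {
      decodeWindows(model, exp$trials[[ho]]$env,
                    list(exp$trials[[ho]]$feats1, exp$trials[[ho]]$feats2),
                    windowSizesS[k], labels = labs[[ho]])
    })
    acc[j, ] <- vapply(results[[j]], decodingAccuracy, 0)
  }
  list(accuracy = acc, results = results, models = models,
       windowSizesS = windowSizesS, heldOut = heldOut,
       labelPolicy = labelPolicy, useTrajectory = useTrajectory)
}
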