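# Windowed decoding: per-component voting between candidate streams,
# channel preference index (CPI), transition times and behavior correction.

#' Constant attention labels (attending the cued stream)
#'
#' @param durationS trial duration in seconds.
#' @param stream attended stream id (default 1, the cued conversation).
#' @param rateHz label rate (default 100).
#' @return an [AttentionLabels-class].
#' @export
cuedLabels <- function(durationS, stream = 1L, rateHz = 100) {
  new("AttentionLabels",
      attendedStream = rep(as.integer(stream), round(durationS * rateHz)),
      lapseIntervals = matrix(numeric(), 0, 2), rateHz = rateHz)
}

#' Decode the attended stream in non-overlapping windows
#'
#' Projects the trial into canonical space, then for each non-overlapping
#' window and each of the first three canonical components, votes for the
#' stream whose projected stimulus correlates more strongly with the
#' projected neural data in that window. The winner is the majority of the
#' three votes (odd count, so no ties between streams; equal component
#' correlations are credited to stream 1, the documented tie-break, and
#' flagged degenerate). CPI = votes for stream 1 / 3 - 0.5.
#'
#' @param model a fitted [CCAModel-class].
#' @param env the held-out trial's [HighGammaEnvelope-class].
#' @param featsList list of the two candidate streams'
#'   [StimFeatures-class] (unnormalized).
#' @param windowSizeS window size in seconds (>= 0.5).
#' @param labels optional [AttentionLabels-class] for accuracy scoring.
#' @return a [DecodingResult-class].
#' @export
decodeWindows <- function(model, env, featsList, windowSizeS,
                          labels = NULL) {
  stopifnot(windowSizeS >= 0.5)
  pr <- projectTrial(model, env, featsList)
  nVote <- min(model@nVoteComponents, ncol(pr$U))
  wf <- round(windowSizeS * 100)
  nW <- floor(nrow(pr$U) / wf)
  if (nW < 1) stop("trial shorter than one window")
  rows <- vector("list", nW)
  lab <- if (!is.null(labels))
    rep(labels@attendedStream, length.out = nrow(pr$U)) else NULL
  for (w in seq_len(nW)) {
    idx <- ((w - 1) * wf + 1):(w * wf)
    c1 <- c2 <- rep(NA_real_, 3)
    for (k in seq_len(nVote)) {
      c1[k] <- cor(pr$U[idx, k], pr$V[[1]][idx, k])
      c2[k] <- cor(pr$U[idx, k], pr$V[[2]][idx, k])
    }
    votes <- sum(c1[seq_len(nVote)] >= c2[seq_len(nVote)])
    winner <- if (votes * 2 >= 3) 1L else 2L
    wl <- if (is.null(lab)) NA_integer_ else {
      tl <- tabulate(lab[idx], 2); which.max(tl)
    }
    rows[[w]] <- data.frame(
      start_s = pr$startS[idx[1]], end_s = pr$startS[idx[1]] + windowSizeS,
      corr1_1 = c1[1], corr1_2 = c1[2], corr1_3 = c1[3],
      corr2_1 = c2[1], corr2_2 = c2[2], corr2_3 = c2[3],
      votes_for_1 = votes, winner = winner, label = wl,
      degenerate = any(c1[seq_len(nVote)] == c2[seq_len(nVote)]))
  }
  win <- do.call(rbind, rows)
  win$cpi <- win$votes_for_1 / 3 - 0.5
  acc <- if (is.null(lab)) NA_real_ else mean(win$winner == win$label)
  new("DecodingResult", windows = win, windowSizeS = windowSizeS,
      accuracy = acc)
}

#' Continuous CPI tracking with a sliding window
#'
#' @param model a fitted [CCAModel-class].
#' @param env trial [HighGammaEnvelope-class].
#' @param featsList two candidate [StimFeatures-class].
#' @param windowSizeS sliding window size (default 4).
#' @param stepS window step (default 0.1).
#' @return data.frame `center_s`, `votes_for_1`, `cpi`.
#' @export
slidingCpi <- function(model, env, featsList, windowSizeS = 4,
                       stepS = 0.1) {
  pr <- projectTrial(model, env, featsList)
  nVote <- min(model@nVoteComponents, ncol(pr$U))
  wf <- round(windowSizeS * 100)
  sf <- round(stepS * 100)
  starts <- seq(1, nrow(pr$U) - wf + 1, by = sf)
  res <- vapply(starts, function(s) {
    idx <- s:(s + wf - 1)
    votes <- 0
    for (k in seq_len(nVote))
      votes <- votes + (cor(pr$U[idx, k], pr$V[[1]][idx, k]) >=
                          cor(pr$U[idx, k], pr$V[[2]][idx, k]))
    votes
  }, 0)
  data.frame(center_s = (starts - 1) / 100 + windowSizeS / 2,
             votes_for_1 = res, cpi = res / 3 - 0.5)
}

#' Transition time of the trial-averaged CPI after a simulated switch
#'
#' Averages CPI series across trials (rows) and returns the first time
#' after the swap instant at which the average crosses 0, linearly
#' interpolated between window centers. NA if the average never crosses.
#'
#' @param cpiMatrix trials x windows matrix of CPI values (or a vector for
#'   a single trial/average).
#' @param centersS window-center times in seconds.
#' @param swapTimeS the simulated switch instant.
#' @return transition time in seconds after the swap, or NA.
#' @export
transitionTime <- function(cpiMatrix, centersS, swapTimeS) {
  avg <- if (is.matrix(cpiMatrix)) colMeans(cpiMatrix) else cpiMatrix
  sgn0 <- sign(mean(avg[centersS <= swapTimeS]))
  if (!is.finite(sgn0) || sgn0 == 0) sgn0 <- 1
  after <- which(centersS > swapTimeS)
  for (j in after) {
    if (avg[j] * sgn0 <= 0) {
      if (j == 1 || avg[j] == 0) return(centersS[j] - swapTimeS)
      t0 <- centersS[j - 1]; t1 <- centersS[j]
      v0 <- avg[j - 1]; v1 <- avg[j]
      tc <- t0 + (0 - v0) / (v1 - v0) * (t1 - t0)
      return(max(tc, swapTimeS) - swapTimeS)
    }
  }
  NA_real_
}

#' Behavior-correct attention labels from button presses
#'
#' If two or more repeated words of the uncued stream were detected
#' (press within the response window), the attended/unattended labels are
#' swapped on the portion bounded by the first and last such press; with
#' fewer than two uncued detections the labels are unchanged. Returns the
#' corrected labels and an audit log of the swaps.
#'
#' @param labels the trial's nominal [AttentionLabels-class] (cued).
#' @param presses a [ButtonPresses-class].
#' @param events repeat-event table (`onset_s`, `stream`), e.g.
#'   [repeatEvents()].
#' @param responseWindowS detection window in seconds (default 2).
#' @param minUncuedDetections swap threshold (default 2).
#' @return list: `labels` (corrected [AttentionLabels-class]), `swapped`
#'   (logical), `interval_s` (the swapped portion or NULL), `nUncuedDetected`.
#' @export
applyBehaviorCorrection <- function(labels, presses, events,
                                    responseWindowS = 2,
                                    minUncuedDetections = 2L) {
  det <- scoreResponses(presses, events, responseWindowS)
  uncued <- det[det$stream != 1L & det$detected, , drop = FALSE]
  if (nrow(uncued) < minUncuedDetections)
    return(list(labels = labels, swapped = FALSE, interval_s = NULL,
                nUncuedDetected = nrow(uncued)))
  t0 <- min(uncued$press_time_s, na.rm = TRUE)
  t1 <- max(uncued$press_time_s, na.rm = TRUE)
  lab <- labels@attendedStream
  idx <- seq_along(lab)
  tt <- (idx - 1) / labels@rateHz
  sel <- tt >= t0 & tt <= t1
  lab[sel] <- 3L - lab[sel]
  out <- initialize(labels, attendedStream = lab)
  list(labels = out, swapped = TRUE, interval_s = c(t0, t1),
       nUncuedDetected = nrow(uncued))
}
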