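# Behavioral scoring of the 1-back repeated-word task and the
# signal-detection sensitivity index.

#' Score button presses against repeated-word events
#'
#' A repeat is detected if a press falls within the response window after
#' its onset. Events are processed in onset order and each press is
#' consumed by at most one event (the earliest eligible event wins, which
#' for rule-compliant scenes is unambiguous because cross-stream onsets
#' are at least 2.5 s apart, wider than the 2 s window).
#'
#' @param presses a [ButtonPresses-class].
#' @param events repeat-event table with `onset_s` and `stream`.
#' @param responseWindowS window in seconds (default 2).
#' @return data.frame: `onset_s`, `stream`, `detected`, `press_time_s`.
#' @export
scoreResponses <- function(presses, events, responseWindowS = 2) {
  ev <- events[order(events$onset_s), , drop = FALSE]
  pt <- presses@pressTimesS
  used <- rep(FALSE, length(pt))
  detected <- logical(nrow(ev))
  pressAt <- rep(NA_real_, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    elig <- which(!used & pt > ev$onset_s[i] &
                    pt <= ev$onset_s[i] + responseWindowS)
    if (length(elig)) {
      j <- elig[1]
      used[j] <- TRUE
      detected[i] <- TRUE
      pressAt[i] <- pt[j]
    }
  }
  data.frame(onset_s = ev$onset_s, stream = ev$stream,
             detected = detected, press_time_s = pressAt)
}

#' Signal-detection sensitivity index d'
#'
#' d' = z(false-alarm rate) - z(hit rate), where z(x) is the standard
#' normal quantile of the right-tail p-value x (so this equals the
#' textbook qnorm(hit) - qnorm(fa) form). Rates are clipped to
#' \[1/(2N), 1 - 1/(2N)\] before the quantiles so perfect rates stay
#' finite.
#'
#' @param hitRate,faRate rates in \[0, 1\].
#' @param nHits,nFas event counts behind each rate (for clipping).
#' @return d' (finite).
#' @export
sensitivityIndex <- function(hitRate, faRate, nHits = 20L, nFas = nHits) {
  clipH <- 1 / (2 * nHits); clipF <- 1 / (2 * nFas)
  h <- min(max(hitRate, clipH), 1 - clipH)
  f <- min(max(faRate, clipF), 1 - clipF)
  zRight <- function(x) qnorm(1 - x)   # right-tail z-score of rate x
  zRight(f) - zRight(h)
}

#' Summarize 1-back behavior for a set of trials
#'
#' @param presses a [ButtonPresses-class] (trial times pooled).
#' @param events repeat-event table (`onset_s`, `stream`).
#' @param cuedStream id of the cued stream (default 1).
#' @param responseWindowS response window (default 2).
#' @return a [BehaviorSummary-class].
#' @export
summarizeBehavior <- function(presses, events, cuedStream = 1L,
                              responseWindowS = 2) {
  det <- scoreResponses(presses, events, responseWindowS)
  cued <- det$stream == cuedStream
  hr <- if (any(cued)) mean(det$detected[cued]) else 0
  fr <- if (any(!cued)) mean(det$detected[!cued]) else 0
  dp <- sensitivityIndex(hr, fr, nHits = max(sum(cued), 1L),
                         nFas = max(sum(!cued), 1L))
  new("BehaviorSummary", hitRate = hr, faRate = fr, dPrime = dp,
      detections = det)
}
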