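# Conversation synthesis: speech-like utterances, turn-taking schedules and
# the 1-back repeated-word insertion rules.

#' Repeated-word insertion rules
#'
#' Defaults encode the insertion criteria of the 1-back task: candidate
#' words of at least 300 ms, 30 ms raised-cosine ramps, 200 ms silence
#' padding, same-stream inter-onset intervals of 5.5-9.5 s, a first onset
#' 5-8 s into the trial, at least 2.5 s between cross-stream onsets,
#' exactly one repeat within 1.5 s after the attended talker switch, and
#' a per-stream count of round(trial duration / 7).
#'
#' @return named list of rule parameters (seconds unless noted).
#' @export
repeatRules <- function() {
  list(minWordS = 0.3, rampS = 0.03, padS = 0.2,
       intervalBoundsS = c(5.5, 9.5), firstOnsetBoundsS = c(5, 8),
       crossStreamGapS = 2.5, postSwitchWindowS = 1.5, countDivisorS = 7,
       maxWordS = 0.55, endMarginS = 1.5)
}

# Sample m values from U(lo, hi) constrained to sum exactly to S.
sampleGapsWithSum <- function(m, lo, hi, S) {
  if (m == 0) return(numeric())
  g <- numeric(m)
  rem <- S
  for (i in seq_len(m)) {
    left <- m - i
    gLo <- max(lo, rem - hi * left)
    gHi <- min(hi, rem - lo * left)
    g[i] <- if (i == m) rem else runif(1, gLo, gHi)
    rem <- rem - g[i]
  }
  g
}

# Intervals allowed for a repeat onset: inside [lo, hi], outside all
# exclusion zones (two-column matrix of open intervals).
allowedIntervals <- function(lo, hi, zones) {
  iv <- matrix(c(lo, hi), 1, 2)
  if (is.null(zones) || nrow(zones) == 0) return(iv)
  zones <- zones[order(zones[, 1]), , drop = FALSE]
  out <- NULL
  cur <- lo
  for (k in seq_len(nrow(zones))) {
    z1 <- zones[k, 1]; z2 <- zones[k, 2]
    if (z2 <= cur || z1 >= hi) next
    if (z1 > cur) out <- rbind(out, c(cur, min(z1, hi)))
    cur <- max(cur, z2)
    if (cur >= hi) break
  }
  if (cur < hi) out <- rbind(out, c(cur, hi))
  if (is.null(out)) matrix(numeric(), 0, 2) else out
}

sampleFromIntervals <- function(iv) {
  len <- iv[, 2] - iv[, 1]
  k <- sample.int(nrow(iv), 1, prob = len)
  runif(1, iv[k, 1], iv[k, 2])
}

#' Plan repeated-word onsets for both streams of a trial
#'
#' Constraint-satisfaction sampler for the repeat-insertion criteria.
#' Returns onsets (in trial time) and repeat word durations per stream;
#' synthesis then builds the speech around these sites.
#'
#' @param trialDurationS trial duration (seconds).
#' @param attendedSwitchS attended talker switch time (default mid-trial).
#' @param unattendedSwitchesS uncued talker switch times (default 25%/75%).
#' @param rules output of [repeatRules()].
#' @param seed integer seed.
#' @param maxTries retry bound before failing.
#' @return list with data.frames `attended` and `unattended`
#'   (`onset_s`, `word_s`) and the switch times used.
#' @export
planRepeatInsertion <- function(trialDurationS,
                                attendedSwitchS = trialDurationS / 2,
                                unattendedSwitchesS =
                                  trialDurationS * c(0.25, 0.75),
                                rules = repeatRules(), seed = 1L,
                                maxTries = 400L) {
  set.seed(seed)
  dur <- trialDurationS
  n <- round(dur / rules$countDivisorS)
  lo <- rules$intervalBoundsS[1]; hi <- rules$intervalBoundsS[2]
  f1 <- rules$firstOnsetBoundsS[1]; f2 <- rules$firstOnsetBoundsS[2]
  gap <- rules$crossStreamGapS
  tEnd <- dur - rules$endMarginS
  sw <- attendedSwitchS
  # boundary exclusion zone half-widths: a repeat needs >= minWord before the
  # onset (plus pad) and >= minWord after it inside one talker segment
  zL <- rules$minWordS                       # copy must end before a boundary
  zR <- rules$minWordS + rules$padS          # source must start after one

  for (attempt in seq_len(maxTries)) {
    # --- attended stream: anchor one repeat just after the talker switch
    rSpec <- sw + runif(1, 0.55, min(1.4, rules$postSwitchWindowS - 0.05))
    ok <- FALSE
    for (m in unique(pmax(0, round((rSpec - (f1 + f2) / 2) / 7.5) + c(0, -1, 1, 2)))) {
      k <- n - 1L - m
      if (k < 0) next
      bLo <- max(lo * m, rSpec - f2); bHi <- min(hi * m, rSpec - f1)
      if (m == 0) { bLo <- 0; bHi <- 0; if (rSpec < f1 || rSpec > f2) next }
      fLo <- lo * k; fHi <- min(hi * k, tEnd - rSpec)
      if (bLo > bHi + 1e-9 || fLo > fHi + 1e-9) next
      Sb <- if (m > 0) runif(1, bLo, bHi) else 0
      Sf <- if (k > 0) runif(1, fLo, fHi) else 0
      gb <- sampleGapsWithSum(m, lo, hi, Sb)
      gf <- sampleGapsWithSum(k, lo, hi, Sf)
      aOn <- sort(c(rSpec - rev(cumsum(gb)), rSpec, rSpec + cumsum(gf)))
      ok <- TRUE
      break
    }
    if (!ok) next
    # --- unattended stream: sequential sampling in the allowed union
    aZones <- cbind(aOn - gap, aOn + gap)
    uswZones <- cbind(unattendedSwitchesS - zL, unattendedSwitchesS + zR)
    zones <- rbind(aZones, uswZones)
    uOn <- numeric(0)
    fail <- FALSE
    for (i in seq_len(n)) {
      wLo <- if (i == 1) f1 else uOn[i - 1] + lo
      wHi <- if (i == 1) min(f2 + 4, tEnd) else min(uOn[i - 1] + hi, tEnd)
      iv <- allowedIntervals(wLo, wHi, zones)
      if (nrow(iv) == 0) { fail <- TRUE; break }
      uOn[i] <- sampleFromIntervals(iv)
    }
    if (fail) next
    # word durations, capped by the enclosing talker segment
    wordFor <- function(r, bounds, special = FALSE, swT = NA) {
      segStart <- max(c(0, bounds[bounds <= r - rules$padS - rules$minWordS]))
      segEnd <- min(c(dur, bounds[bounds > r]))
      loW <- rules$minWordS
      hiW <- min(rules$maxWordS, r - rules$padS - segStart, segEnd - r)
      if (special) hiW <- min(hiW, r - swT - rules$padS - 0.02)
      if (hiW < loW) return(NA_real_)
      runif(1, loW, hiW)
    }
    aW <- vapply(aOn, wordFor, 0, bounds = sw,
                 special = FALSE)
    iSpec <- which.min(abs(aOn - rSpec))
    aW[iSpec] <- wordFor(aOn[iSpec], bounds = sw, special = TRUE, swT = sw)
    uW <- vapply(uOn, wordFor, 0, bounds = unattendedSwitchesS)
    if (any(is.na(aW)) || any(is.na(uW))) next
    return(list(
      attended = data.frame(onset_s = aOn, word_s = aW),
      unattended = data.frame(onset_s = uOn, word_s = uW),
      attendedSwitchS = sw, unattendedSwitchesS = unattendedSwitchesS,
      nRepeats = n, attempts = attempt))
  }
  stop("repeat insertion failed: could not satisfy inter-onset interval ",
       "and cross-stream gap criteria within the retry bound")
}

#' Talker voice profile for the speech-like synthesizer
#'
#' @param f0Hz fundamental frequency in Hz.
#' @param formantsHz centers of the formant-like spectral peaks.
#' @return named list.
#' @export
talkerProfile <- function(f0Hz, formantsHz = c(500, 1500, 2500) *
                            (f0Hz / 150)^0.25) {
  list(f0Hz = f0Hz, formantsHz = formantsHz)
}

# One word: harmonic-plus-noise signal with vibrato, formant-shaped
# harmonic amplitudes, syllabic AM and edge ramps. Uses the active RNG.
synthWordWave <- function(profile, durS, fs) {
  n <- max(8L, round(durS * fs))
  t <- (seq_len(n) - 1) / fs
  f0 <- profile$f0Hz * (1 + 0.03 * sin(2 * pi * runif(1, 2.5, 4) * t +
                                       runif(1, 0, 2 * pi)) +
                          0.01 * rnorm(1))
  phase0 <- 2 * pi * cumsum(f0) / fs
  nh <- max(3L, floor(4000 / profile$f0Hz))
  h <- seq_len(nh)
  fh <- outer(rep(1, n), h * profile$f0Hz)
  gain <- (1 / h)
  for (fc in profile$formantsHz)
    gain <- gain + 1.5 * exp(-((h * profile$f0Hz - fc)^2) / (2 * 200^2))
  x <- sin(outer(phase0, h)) %*% (gain * runif(nh, 0.7, 1))
  x <- as.numeric(x) + 0.08 * rnorm(n) * max(abs(x)) / 3
  am <- 0.75 + 0.25 * sin(2 * pi * runif(1, 3, 6) * t + runif(1, 0, 2 * pi))
  x <- x * am
  x <- applyRamps(x, fs, 0.02)
  x / max(rmsLevel(x), 1e-9) * 0.15
}

#' Synthesize a speech-like utterance with word intervals
#'
#' Amplitude-modulated harmonic-plus-noise "speech" with silences at word
#' boundaries; a fixture-grade stand-in for recorded voice actors.
#' Deterministic for a given seed.
#'
#' @param profile a [talkerProfile()].
#' @param durationS utterance duration (>= 1 s).
#' @param wordGridS numeric vector of word durations in seconds; words are
#'   laid out with short gaps and the remainder is silence.
#' @param seed integer seed.
#' @param fsHz waveform sampling rate (default 16000).
#' @return list: `wave` (numeric) and `words` (data.frame `onset_s`,
#'   `offset_s`).
#' @export
synthSpeechlikeUtterance <- function(profile, durationS, wordGridS,
                                     seed = 1L, fsHz = 16000) {
  stopifnot(durationS >= 1)
  set.seed(seed)
  n <- round(durationS * fsHz)
  wave <- numeric(n)
  cursor <- 0.05
  onsets <- offsets <- numeric(0)
  for (dw in wordGridS) {
    if (cursor + dw > durationS - 0.02) break
    w <- synthWordWave(profile, dw, fsHz)
    i0 <- round(cursor * fsHz) + 1
    wave[i0:(i0 + length(w) - 1)] <- w
    onsets <- c(onsets, cursor); offsets <- c(offsets, cursor + dw)
    cursor <- cursor + dw + runif(1, 0.05, 0.15)
  }
  list(wave = wave, words = data.frame(onset_s = onsets, offset_s = offsets))
}

# Build one conversation stream's mono waveform around planned repeat sites.
# Returns the waveform, word table and repeat-event table (trial time).
buildStreamWave <- function(durS, startS, switchTimesS, plan, talkers, fs,
                            streamId) {
  n <- round(durS * fs)
  wave <- numeric(n)
  bounds <- c(startS, switchTimesS, durS)
  talkerAt <- function(t) talkers[[min(length(talkers),
                                       findInterval(t, bounds,
                                                    rightmost.closed = TRUE))]]
  rows <- list()
  put <- function(w, at) {
    i0 <- round(at * fs) + 1
    i1 <- i0 + length(w) - 1
    if (i1 <= n) wave[i0:i1] <<- wave[i0:i1] + w
  }
  fillWords <- function(from, to) {
    cursor <- from
    segB <- sort(c(bounds[bounds > from & bounds < to], to))
    for (b in segB) {
      while (cursor + 0.15 < b) {
        dw <- min(runif(1, 0.22, 0.6), b - cursor - 0.02)
        if (dw < 0.12) break
        tk <- talkerAt(cursor)
        w <- synthWordWave(tk$profile, dw, fs)
        put(w, cursor)
        rows[[length(rows) + 1]] <<- data.frame(
          onset_s = cursor, offset_s = cursor + dw, talker = tk$id,
          is_repeat_source = FALSE, is_repeat_copy = FALSE)
        cursor <- cursor + dw + runif(1, 0.06, 0.18)
      }
      cursor <- max(cursor, b + 0.02)
    }
  }
  pad <- 0.2; ramp <- 0.03
  cursor <- startS + 0.05
  plan <- plan[order(plan$onset_s), , drop = FALSE]
  events <- list()
  for (k in seq_len(nrow(plan))) {
    r <- plan$onset_s[k]; dw <- plan$word_s[k]
    srcStart <- r - pad - dw
    fillWords(cursor, srcStart - 0.02)
    tk <- talkerAt(srcStart)
    w <- synthWordWave(tk$profile, dw, fs)
    put(w, srcStart)
    copy <- applyRamps(w, fs, ramp)   # the repeat replicates the source wave
    put(copy, r)
    rows[[length(rows) + 1]] <- data.frame(
      onset_s = srcStart, offset_s = srcStart + dw, talker = tk$id,
      is_repeat_source = TRUE, is_repeat_copy = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      onset_s = r, offset_s = r + dw, talker = tk$id,
      is_repeat_source = FALSE, is_repeat_copy = TRUE)
    events[[k]] <- data.frame(onset_s = r, duration_s = dw,
                              stream = streamId)
    cursor <- r + dw + pad
  }
  fillWords(cursor, durS - 0.05)
  words <- do.call(rbind, rows)
  words <- words[order(words$onset_s), ]
  rownames(words) <- NULL
  script <- new("ConversationScript", words = words,
                switchTimesS = switchTimesS,
                repeatEvents = do.call(rbind, events),
                streamId = as.integer(streamId))
  list(wave = wave, script = script)
}

#' Build both conversation streams of a trial
#'
#' Plans repeat insertion, assigns four talker voices (two per stream),
#' and synthesizes the two mono conversation waveforms with turn-taking:
#' the cued stream switches talker at ~50% trial time; the uncued stream
#' (starting `uncuedDelayS` late) switches at ~25% and ~75%.
#'
#' @param trialDurationS trial duration (seconds).
#' @param uncuedDelayS uncued onset lag (default 3).
#' @param rules [repeatRules()].
#' @param seed integer seed.
#' @param fsHz sampling rate (default 16000).
#' @return list: `wave1`, `wave2` (mono), `scripts` (list of two
#'   [ConversationScript-class]), `plan`.
#' @export
buildConversationPair <- function(trialDurationS, uncuedDelayS = 3,
                                  rules = repeatRules(), seed = 1L,
                                  fsHz = 16000) {
  plan <- planRepeatInsertion(trialDurationS, seed = seed, rules = rules)
  set.seed(seed + 7654321L)
  f0s <- c(sample(c(105, 125), 2), sample(c(190, 225), 2))[sample.int(4)]
  mk <- function(id, f0) list(id = id, profile = talkerProfile(f0))
  s1 <- buildStreamWave(trialDurationS, 0, plan$attendedSwitchS,
                        plan$attended,
                        list(mk("A", f0s[1]), mk("B", f0s[2])), fsHz, 1L)
  s2 <- buildStreamWave(trialDurationS, uncuedDelayS,
                        plan$unattendedSwitchesS, plan$unattended,
                        list(mk("C", f0s[3]), mk("D", f0s[4]),
                             mk("C", f0s[3])), fsHz, 2L)
  list(wave1 = s1$wave, wave2 = s2$wave,
       scripts = list(s1$script, s2$script), plan = plan)
}
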