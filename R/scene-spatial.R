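# Binaural rendering (spherical-head ITD/ILD surrogate), background-noise
# surrogates, and trial-scene assembly/auditing.

#' Woodworth spherical-head interaural time difference
#'
#' ITD(theta) = (a / c) * (sin(theta) + theta) seconds for azimuth theta in
#' radians; positive azimuths (left) give positive ITD (left ear leads).
#'
#' @param azimuthDeg azimuth in degrees, in \[-90, 90\].
#' @param headRadiusM head radius in meters (default 0.0875).
#' @param soundSpeedMps speed of sound (default 343).
#' @return ITD in seconds (signed).
#' @export
woodworthItd <- function(azimuthDeg, headRadiusM = 0.0875,
                         soundSpeedMps = 343) {
  th <- azimuthDeg * pi / 180
  headRadiusM / soundSpeedMps * (sin(th) + th)
}

#' Spatialize a mono waveform along a trajectory
#'
#' Surrogate binaural renderer: per-sample fractional-delay ITD from the
#' Woodworth spherical-head model plus an azimuth-dependent broadband ILD
#' (`ildMaxDb * sin(theta)` level difference). At azimuth 0 the two output
#' channels are identical; the left channel leads (and is louder) for
#' positive (left) azimuths.
#'
#' @param mono numeric waveform.
#' @param traj a [Trajectory-class] covering the signal duration.
#' @param fsHz waveform sampling rate.
#' @param headRadiusM head radius in meters (default 0.0875).
#' @param ildMaxDb broadband level difference at +/-90 degrees (default 10).
#' @return a [BinauralSignal-class].
#' @export
spatialize <- function(mono, traj, fsHz, headRadiusM = 0.0875,
                       ildMaxDb = 10) {
  if (max(abs(traj@azimuthDeg)) > 90 + 1e-9)
    stop("|azimuth| > 90 degrees is outside the frontal half plane")
  n <- length(mono)
  t <- (seq_len(n) - 1) / fsHz
  az <- azimuthAt(traj, t)
  itd <- woodworthItd(az, headRadiusM)
  # left ear leads for positive azimuth: it hears the source earlier
  left <- approx(t, mono, xout = t + itd / 2, rule = 2)$y
  right <- approx(t, mono, xout = t - itd / 2, rule = 2)$y
  ild <- ildMaxDb * sin(az * pi / 180)
  left <- left * 10^(ild / 40)
  right <- right * 10^(-ild / 40)
  new("BinauralSignal", left = left, right = right, fsHz = fsHz)
}

#' Background-noise surrogates
#'
#' `pedestrian`: pink noise with sparse transient bursts. `babble`: the sum
#' of eight speech-like utterance streams. Output is mono at unit RMS;
#' [mixScene()] duplicates it diotically and sets its level.
#'
#' @param durationS noise duration in seconds.
#' @param type `"pedestrian"` or `"babble"`.
#' @param fsHz sampling rate.
#' @param seed integer seed.
#' @return numeric mono waveform, unit RMS.
#' @export
backgroundNoise <- function(durationS, type = c("pedestrian", "babble"),
                            fsHz = 16000, seed = 1L) {
  type <- match.arg(type)
  set.seed(seed)
  n <- round(durationS * fsHz)
  if (type == "pedestrian") {
    x <- pinkNoise(n)
    nBurst <- rpois(1, durationS / 4)
    for (b in seq_len(nBurst)) {
      at <- runif(1, 0, durationS - 0.3)
      len <- round(runif(1, 0.05, 0.25) * fsHz)
      i0 <- round(at * fsHz) + 1
      burst <- applyRamps(rnorm(len), fsHz, 0.01) * runif(1, 2, 4)
      x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] + burst
    }
  } else {
    x <- numeric(n)
    for (k in 1:8) {
      prof <- talkerProfile(runif(1, 100, 240))
      grid <- runif(ceiling(durationS / 0.45), 0.2, 0.5)
      u <- synthSpeechlikeUtterance(prof, durationS, grid,
                                    seed = seed * 131L + k, fsHz = fsHz)
      x <- x + u$wave
    }
  }
  x / max(rmsLevel(x), 1e-12)
}

# Per-channel power of a stereo stream over its active support.
streamPower <- function(bs, support = NULL) {
  if (is.null(support)) support <- which(bs@left != 0 | bs@right != 0)
  mean((bs@left[support]^2 + bs@right[support]^2) / 2)
}

scaleBinaural <- function(bs, g)
  new("BinauralSignal", left = bs@left * g, right = bs@right * g,
      fsHz = bs@fsHz)

#' Mix two spatialized conversation streams with diotic background noise
#'
#' Equalizes the two conversation streams to equal RMS over their active
#' supports, scales the noise so its per-channel power sits
#' `|noiseLevelDb|` dB below a conversation stream, and sums everything
#' into the mixture (y = s1 + s2 + n).
#'
#' @param conv1,conv2 spatialized [BinauralSignal-class] streams (conv2
#'   already carries its onset delay as leading silence).
#' @param noiseMono mono noise waveform (any scale).
#' @param noiseLevelDb -9 or -12.
#' @param trajectories a [TrajectoryPair-class] for the scene record.
#' @param scripts list of two [ConversationScript-class] objects.
#' @param uncuedDelayS uncued onset lag in seconds (default 3).
#' @param meta extra metadata list.
#' @return a [TrialScene-class].
#' @export
mixScene <- function(conv1, conv2, noiseMono, noiseLevelDb = -9,
                     trajectories, scripts, uncuedDelayS = 3, meta = list()) {
  if (!noiseLevelDb %in% c(-9, -12))
    stop("noiseLevelDb must be -9 or -12 dB")
  p1 <- streamPower(conv1)
  conv2 <- scaleBinaural(conv2, sqrt(p1 / streamPower(conv2)))
  pn <- p1 * 10^(noiseLevelDb / 10)
  noiseMono <- noiseMono * sqrt(pn / mean(noiseMono^2))
  noise <- new("BinauralSignal", left = noiseMono, right = noiseMono,
               fsHz = conv1@fsHz)
  mix <- new("BinauralSignal",
             left = conv1@left + conv2@left + noise@left,
             right = conv1@right + conv2@right + noise@right,
             fsHz = conv1@fsHz)
  new("TrialScene", mixture = mix, conv1 = conv1, conv2 = conv2,
      noise = noise, trajectories = trajectories, scripts = scripts,
      noiseLevelDb = noiseLevelDb, uncuedDelayS = uncuedDelayS, meta = meta)
}

#' Build a complete trial scene
#'
#' End-to-end generator: trial duration drawn from Normal(44.2 s, 2.0 s)
#' truncated to \[40, 50\] (unless given), a criteria-passing trajectory
#' pair, two turn-taking conversations with inserted repeated words,
#' spherical-head spatialization, and diotic background noise. Bit-identical
#' for a given seed and configuration.
#'
#' @param seed integer seed.
#' @param durationS optional fixed trial duration.
#' @param noiseLevelDb -9 or -12 (default -9).
#' @param noiseType `"pedestrian"` or `"babble"`.
#' @param fsHz sampling rate (default 16000).
#' @param uncuedDelayS uncued conversation onset lag (default 3).
#' @return a [TrialScene-class].
#' @export
buildTrialScene <- function(seed = 1L, durationS = NULL, noiseLevelDb = -9,
                            noiseType = "pedestrian", fsHz = 16000,
                            uncuedDelayS = 3) {
  set.seed(seed)
  if (is.null(durationS)) {
    repeat {
      durationS <- rnorm(1, 44.2, 2.0)
      if (durationS >= 40 && durationS <= 50) break
    }
  }
  pair <- generateTrajectoryPair(durationS, uncuedOnsetS = uncuedDelayS,
                                 attendedSwitchS = durationS / 2,
                                 seed = seed)
  conv <- buildConversationPair(durationS, uncuedDelayS = uncuedDelayS,
                                seed = seed, fsHz = fsHz)
  s1 <- spatialize(conv$wave1, pair@trajA, fsHz)
  s2 <- spatialize(conv$wave2, pair@trajB, fsHz)
  noise <- backgroundNoise(durationS, noiseType, fsHz, seed = seed + 999L)
  mixScene(s1, s2, noise, noiseLevelDb, pair, conv$scripts,
           uncuedDelayS = uncuedDelayS,
           meta = list(seed = seed, durationS = durationS,
                       noiseType = noiseType, fsHz = fsHz,
                       mono1 = conv$wave1, mono2 = conv$wave2,
                       plan = conv$plan))
}

#' Audit a trial scene against the generation criteria
#'
#' Independent re-check (it does not reuse the inserter's intermediate
#' state) of the nine repeat-insertion criteria, the three trajectory-pair
#' criteria, the uncued onset lag, the equal-RMS constraint and the noise
#' level.
#'
#' @param scene a [TrialScene-class].
#' @param rules [repeatRules()].
#' @return data.frame with columns `check`, `value`, `pass`.
#' @export
auditTrialScene <- function(scene, rules = repeatRules()) {
  fs <- scene@mixture@fsHz
  dur <- durationS(scene@mixture)
  ev <- repeatEvents(scene)
  e1 <- ev[ev$stream == 1, ]; e2 <- ev[ev$stream == 2, ]
  out <- list()
  add <- function(check, value, pass)
    out[[length(out) + 1]] <<- data.frame(check = check, value = value,
                                          pass = pass)
  nExp <- round(dur / rules$countDivisorS)
  add("repeat_count_stream1", nrow(e1), nrow(e1) == nExp)
  add("repeat_count_stream2", nrow(e2), nrow(e2) == nExp)
  add("equal_counts", nrow(e1) - nrow(e2), nrow(e1) == nrow(e2))
  add("min_word_duration_s", min(ev$duration_s),
      min(ev$duration_s) >= rules$minWordS - 1e-9)
  gaps <- c(diff(e1$onset_s), diff(e2$onset_s))
  add("same_stream_gap_min_s", min(gaps),
      min(gaps) >= rules$intervalBoundsS[1] - 1e-6)
  add("same_stream_gap_max_s", max(gaps),
      max(gaps) <= rules$intervalBoundsS[2] + 1e-6)
  add("first_onset_s", min(ev$onset_s),
      min(ev$onset_s) >= rules$firstOnsetBoundsS[1] - 1e-6 &&
        min(ev$onset_s) <= rules$firstOnsetBoundsS[2] + 1e-6)
  cross <- outer(e1$onset_s, e2$onset_s, function(a, b) abs(a - b))
  add("cross_stream_gap_min_s", min(cross),
      min(cross) >= rules$crossStreamGapS - 1e-6)
  sw <- scene@scripts[[1]]@switchTimesS[1]
  inWin <- sum(e1$onset_s > sw & e1$onset_s <= sw + rules$postSwitchWindowS)
  add("attended_post_switch_repeats", inWin, inWin == 1)
  # ramp + pad checks on the mono waveforms stored in meta
  if (!is.null(scene@meta$mono1)) {
    mono <- list(scene@meta$mono1, scene@meta$mono2)
    padOk <- rampOk <- TRUE
    for (s in 1:2) {
      sc <- scene@scripts[[s]]
      copies <- sc@words[sc@words$is_repeat_copy, ]
      sources <- sc@words[sc@words$is_repeat_source, ]
      for (k in seq_len(nrow(copies))) {
        i0 <- round(copies$onset_s[k] * fs) + 1
        nW <- round((copies$offset_s[k] - copies$onset_s[k]) * fs)
        # pad interior with a 2-sample guard for onset rounding jitter
        pre <- mono[[s]][max(1, i0 - round(rules$padS * fs) + 2):(i0 - 2)]
        post <- mono[[s]][(i0 + nW + 1):min(length(mono[[s]]),
                                            i0 + nW + round(rules$padS * fs) - 2)]
        if (max(abs(pre), abs(post)) > 1e-9) padOk <- FALSE
        j0 <- round(sources$onset_s[k] * fs) + 1
        src <- mono[[s]][j0:(j0 + nW - 1)]
        cpy <- mono[[s]][i0:(i0 + nW - 1)]
        if (max(abs(cpy - applyRamps(src, fs, rules$rampS))) > 1e-9)
          rampOk <- FALSE
      }
    }
    add("repeat_pads_silent", NA_real_, padOk)
    add("repeat_hann_ramps", NA_real_, rampOk)
  }
  # trajectory-pair criteria
  pair <- checkPairCriteria(scene@trajectories, scene@uncuedDelayS, sw)
  add("trajectory_criteria", NA_real_, pair@criteriaReport$pass[4])
  # uncued onset lag exact at sample resolution
  on1 <- which(scene@meta$mono1 != 0)[1]
  on2 <- which(scene@meta$mono2 != 0)[1]
  lag <- (on2 - on1) / fs
  add("uncued_onset_lag_s", lag,
      abs((on2 - on1) - round(scene@uncuedDelayS * fs)) == 0)
  # equal conversation RMS over active supports
  r1 <- sqrt(streamPower(scene@conv1)); r2 <- sqrt(streamPower(scene@conv2))
  add("conv_rms_ratio", r1 / r2, abs(r1 / r2 - 1) < 1e-3)
  # noise level
  lev <- db(streamPower(scene@noise) / streamPower(scene@conv1))
  add("noise_level_db", lev, abs(lev - scene@noiseLevelDb) < 0.1)
  add("noise_diotic", NA_real_,
      identical(scene@noise@left, scene@noise@right))
  do.call(rbind, out)
}
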