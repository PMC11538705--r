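# Neural preprocessing: reference montage, line-noise removal, high-gamma
# envelope extraction at 100 Hz, and speech-responsive electrode selection.

#' Construct a NeuralRecording
#'
#' @param data channels x time matrix (microvolts).
#' @param fsHz sampling rate.
#' @param channelLabels optional channel identifiers.
#' @return a [NeuralRecording-class].
#' @export
neuralRecording <- function(data, fsHz, channelLabels = NULL) {
  if (is.null(channelLabels))
    channelLabels <- sprintf("ch%03d", seq_len(nrow(data)))
  new("NeuralRecording", data = data, fsHz = fsHz,
      channelLabels = channelLabels)
}

# Zero-phase multi-notch filter at 60/120/180 Hz: order-1000 FIR designed
# from a piecewise magnitude response (fir2) and applied with filtfilt.
notchLineNoise <- function(mat, fs, lines = c(60, 120, 180), order = 1000,
                           halfWidth = 1.5) {
  lines <- lines[lines < fs / 2 - 2]
  f <- c(0)
  m <- c(1)
  for (L in lines) {
    f <- c(f, (L - 2 * halfWidth) / (fs / 2), (L - halfWidth) / (fs / 2),
           (L + halfWidth) / (fs / 2), (L + 2 * halfWidth) / (fs / 2))
    m <- c(m, 1, 0, 0, 1)
  }
  f <- c(f, 1); m <- c(m, 1)
  b <- signal::fir2(order, f, m)
  t(apply(mat, 1, function(x) signal::filtfilt(b, x)))
}

#' Standardize a raw neural recording
#'
#' Resamples to 1000 Hz, applies a common average reference (per-sample
#' cross-channel mean subtraction), downsamples to 400 Hz and removes
#' 60/120/180 Hz line noise with a zero-phase order-1000 FIR notch.
#'
#' @param rec a [NeuralRecording-class] with at least 2 channels.
#' @return a [NeuralRecording-class] at 400 Hz.
#' @export
standardizeRecording <- function(rec) {
  if (nrow(rec@data) < 2)
    stop("common average reference requires at least 2 channels")
  x <- resampleRows(rec@data, rec@fsHz, 1000)
  x <- sweep(x, 2, colMeans(x))          # CAR
  x <- resampleRows(x, 1000, 400)
  x <- notchLineNoise(x, 400)
  neuralRecording(x, 400, rec@channelLabels)
}

# The eight consecutive 10 Hz-wide high-gamma sub-bands.
highGammaBands <- function() cbind(lo = seq(70, 140, by = 10),
                                   hi = seq(80, 150, by = 10))

# Zero-phase FIR band-pass for one sub-band at fs = 400 Hz.
subBandFilter <- function(lo, hi, fs = 400, order = 300) {
  signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
}

#' Extract 100 Hz high-gamma envelopes
#'
#' Filters 400 Hz neural data through a bank of eight 10 Hz-wide zero-phase
#' FIR band-passes spanning 70-150 Hz, takes the magnitude of the analytic
#' signal of each sub-band, averages the eight envelopes and resamples the
#' result to 100 Hz (clipped at 0 against resampling undershoot).
#'
#' @param rec a [NeuralRecording-class] at 400 Hz (e.g. from
#'   [standardizeRecording()]).
#' @param filterOrder FIR order of each sub-band filter (default 300).
#' @return a [HighGammaEnvelope-class].
#' @export
highGammaEnvelope <- function(rec, filterOrder = 300) {
  if (abs(rec@fsHz - 400) > 1e-6)
    stop("high-gamma extraction expects a 400 Hz recording")
  if (ncol(rec@data) < 4 * filterOrder)
    stop("signal shorter than the filter transient support")
  bands <- highGammaBands()
  filt <- lapply(seq_len(nrow(bands)),
                 function(i) subBandFilter(bands[i, 1], bands[i, 2],
                                           order = filterOrder))
  env <- matrix(0, nrow(rec@data), ncol(rec@data))
  for (b in seq_along(filt)) {
    for (ch in seq_len(nrow(rec@data))) {
      y <- signal::filtfilt(filt[[b]], rec@data[ch, ])
      env[ch, ] <- env[ch, ] + amplitudeEnvelope(y)
    }
  }
  env <- env / length(filt)
  env <- resampleRows(env, 400, 100)
  env[env < 0] <- 0
  new("HighGammaEnvelope", env = env, fsHz = 100, bandEdges = bands)
}

#' Select speech-responsive electrodes
#'
#' For each trial onset, draws 25 random envelope samples from a silence
#' window (-0.4 to -0.1 s) and 25 from a speech window (0.1 to 1.6 s),
#' pools them across trials, and computes a two-sample pooled-variance t
#' statistic (speech minus silence) per channel. Channels with t above the
#' threshold are speech-responsive.
#'
#' @param env a [HighGammaEnvelope-class].
#' @param trialOnsetsS speech onset times in seconds.
#' @param threshold t threshold (default 5).
#' @param nSamples samples drawn per window per trial (default 25).
#' @param seed integer seed for the random draw.
#' @param replace draw with replacement (default FALSE).
#' @return an [ElectrodeSelection-class].
#' @export
selectSpeechResponsive <- function(env, trialOnsetsS, threshold = 5,
                                   nSamples = 25, seed = 1L,
                                   replace = FALSE) {
  fs <- env@fsHz
  nT <- ncol(env@env)
  set.seed(seed)
  silIdx <- speIdx <- integer(0)
  for (on in trialOnsetsS) {
    sil <- round((on - 0.4) * fs):round((on - 0.1) * fs) + 1L
    spe <- round((on + 0.1) * fs):round((on + 1.6) * fs) + 1L
    if (min(sil) < 1 || max(spe) > nT)
      stop(sprintf("windows around trial onset %.2f s are out of range", on))
    silIdx <- c(silIdx, sample(sil, nSamples, replace = replace))
    speIdx <- c(speIdx, sample(spe, nSamples, replace = replace))
  }
  tStats <- vapply(seq_len(nrow(env@env)), function(ch) {
    unname(t.test(env@env[ch, speIdx], env@env[ch, silIdx],
                  var.equal = TRUE)$statistic)
  }, 0)
  names(tStats) <- rownames(env@env)
  new("ElectrodeSelection", tStats = tStats, selected = tStats > threshold,
      threshold = threshold)
}
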