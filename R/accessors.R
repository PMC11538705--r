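# Accessors and show methods.

#' @describeIn Trajectory sampling rate in Hz.
#' @param x object.
#' @export
setMethod("samplingRate", "Trajectory", function(x) x@rateHz)

#' @describeIn BinauralSignal sampling rate in Hz.
#' @param x object.
#' @export
setMethod("samplingRate", "BinauralSignal", function(x) x@fsHz)

#' @describeIn NeuralRecording sampling rate in Hz.
#' @param x object.
#' @export
setMethod("samplingRate", "NeuralRecording", function(x) x@fsHz)

#' @describeIn HighGammaEnvelope sampling rate in Hz (always 100).
#' @param x object.
#' @export
setMethod("samplingRate", "HighGammaEnvelope", function(x) x@fsHz)

#' @describeIn Trajectory duration in seconds.
#' @export
setMethod("durationS", "Trajectory",
          function(x) length(x@azimuthDeg) / x@rateHz)

#' @describeIn BinauralSignal duration in seconds.
#' @export
setMethod("durationS", "BinauralSignal", function(x) length(x@left) / x@fsHz)

#' @describeIn NeuralRecording duration in seconds.
#' @export
setMethod("durationS", "NeuralRecording", function(x) ncol(x@data) / x@fsHz)

#' @describeIn HighGammaEnvelope duration in seconds.
#' @export
setMethod("durationS", "HighGammaEnvelope", function(x) ncol(x@env) / x@fsHz)

#' @describeIn Trajectory the azimuth series in degrees.
#' @export
setMethod("azimuth", "Trajectory", function(x) x@azimuthDeg)

#' @describeIn Trajectory azimuth at arbitrary times by linear interpolation.
#' @param timesS times in seconds.
#' @export
setMethod("azimuthAt", "Trajectory", function(x, timesS) {
  tGrid <- x@t0S + (seq_along(x@azimuthDeg) - 1) / x@rateHz
  interpSeries(tGrid, x@azimuthDeg, timesS)
})

#' Left channel of a binaural signal
#' @param x a [BinauralSignal-class].
#' @return numeric waveform.
#' @export
leftChannel <- function(x) x@left

#' Right channel of a binaural signal
#' @param x a [BinauralSignal-class].
#' @return numeric waveform.
#' @export
rightChannel <- function(x) x@right

#' Envelope matrix of a HighGammaEnvelope
#' @param x a [HighGammaEnvelope-class].
#' @return channels x time matrix.
#' @export
envelopeMatrix <- function(x) x@env

#' Repeat events of a trial scene
#'
#' @param scene a [TrialScene-class].
#' @return data.frame with `onset_s`, `duration_s`, `stream`, sorted by onset.
#' @export
repeatEvents <- function(scene) {
  ev <- do.call(rbind, lapply(scene@scripts, function(s) s@repeatEvents))
  ev[order(ev$onset_s), , drop = FALSE]
}

#' Per-window decoding table of a DecodingResult
#' @param x a [DecodingResult-class].
#' @return data.frame, one row per window.
#' @export
decodingWindows <- function(x) x@windows

#' Decoding accuracy of a DecodingResult
#' @param x a [DecodingResult-class].
#' @return fraction of windows decoded correctly.
#' @export
decodingAccuracy <- function(x) x@accuracy

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d samples at %g Hz (%.1f s), azimuth [%.1f, %.1f] deg\n",
              length(object@azimuthDeg), object@rateHz, durationS(object),
              min(object@azimuthDeg), max(object@azimuthDeg)))
})

setMethod("show", "TrajectoryPair", function(object) {
  cat("TrajectoryPair\n")
  show(object@trajA); show(object@trajB)
  if (nrow(object@criteriaReport)) {
    cat("criteria:\n"); print(object@criteriaReport)
  }
})

setMethod("show", "BinauralSignal", function(object) {
  cat(sprintf("BinauralSignal: %d samples at %g Hz (%.2f s)\n",
              length(object@left), object@fsHz, durationS(object)))
})

setMethod("show", "TrialScene", function(object) {
  cat(sprintf(
    "TrialScene: %.1f s at %g Hz, noise %g dB, uncued lag %g s, %d repeats\n",
    durationS(object@mixture), object@mixture@fsHz, object@noiseLevelDb,
    object@uncuedDelayS, nrow(repeatEvents(object))))
})

setMethod("show", "NeuralRecording", function(object) {
  cat(sprintf("NeuralRecording: %d channels x %d samples at %g Hz\n",
              nrow(object@data), ncol(object@data), object@fsHz))
})

setMethod("show", "HighGammaEnvelope", function(object) {
  cat(sprintf("HighGammaEnvelope: %d channels x %d frames at %g Hz (%d bands)\n",
              nrow(object@env), ncol(object@env), object@fsHz,
              nrow(object@bandEdges)))
})

setMethod("show", "ElectrodeSelection", function(object) {
  cat(sprintf("ElectrodeSelection: %d / %d channels with t > %g\n",
              sum(object@selected), length(object@selected), object@threshold))
})

setMethod("show", "CCAModel", function(object) {
  cat(sprintf(
    "CCAModel: %d canonical components (top r = %.3f), lags %d/%d, %s\n",
    length(object@canCors), object@canCors[1], object@neuralLags,
    object@stimLags,
    if (object@useTrajectory) "spectrogram+trajectory" else "spectrogram-only"))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: %d windows of %g s, accuracy %.3f\n",
              nrow(object@windows), object@windowSizeS, object@accuracy))
})

setMethod("show", "GainSolution", function(object) {
  cat(sprintf("GainSolution: k = %.5f, alpha_att = %.5f, alpha_unatt = %g (%g dB)\n",
              object@k, object@alphaAttended, object@alphaUnattended,
              object@suppressionDb))
})

setMethod("show", "BehaviorSummary", function(object) {
  cat(sprintf("BehaviorSummary: hit %.3f, FA %.3f, d' = %.2f\n",
              object@hitRate, object@faRate, object@dPrime))
})
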