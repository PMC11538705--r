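# Central S4 containers. Validity methods enforce the contracts that the
# rest of the toolkit assumes; constructors live next to the module code.

#' Trajectory: an azimuth path of one conversation
#'
#' Azimuth-versus-time series confined to the frontal half of the horizontal
#' plane (azimuths in degrees, -90 = right, +90 = left).
#'
#' @slot azimuthDeg numeric vector of azimuths in degrees, all in \[-90, 90\].
#' @slot rateHz sampling rate of the series (samples/second).
#' @slot t0S start-time offset in seconds.
#' @export
setClass("Trajectory",
  representation(azimuthDeg = "numeric", rateHz = "numeric", t0S = "numeric"),
  prototype(azimuthDeg = numeric(), rateHz = 0.5, t0S = 0))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@rateHz) != 1 || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive number")
  if (any(!is.finite(object@azimuthDeg)))
    msg <- c(msg, "azimuths must be finite")
  else if (length(object@azimuthDeg) &&
           (min(object@azimuthDeg) < -90 - 1e-9 ||
            max(object@azimuthDeg) > 90 + 1e-9))
    msg <- c(msg, "azimuths must lie in [-90, 90] degrees")
  if (length(msg)) msg else TRUE
})

#' TrajectoryPair: the spatial paths of the two conversations of a trial
#'
#' @slot trajA,trajB [Trajectory-class] objects sharing rate and duration.
#' @slot criteriaReport data.frame of per-criterion measured values and
#'   pass flags (empty until [checkPairCriteria()] has been run).
#' @export
setClass("TrajectoryPair",
  representation(trajA = "Trajectory", trajB = "Trajectory",
                 criteriaReport = "data.frame"),
  prototype(criteriaReport = data.frame()))

setValidity("TrajectoryPair", function(object) {
  if (abs(object@trajA@rateHz - object@trajB@rateHz) > 1e-9)
    return("trajectories must share a sampling rate")
  if (abs(length(object@trajA@azimuthDeg) - length(object@trajB@azimuthDeg)) > 1)
    return("trajectories must share a duration (lengths within 1 sample)")
  TRUE
})

#' MarkovChainConfig: first-order chain generating azimuth trajectories
#'
#' The chain walks on a 1-degree grid over \[-90, 90\] (181 states). The
#' transition kernel is a local random-walk profile: probability mass on
#' steps within +/- `stepSpan` states, renormalized at the grid edges.
#'
#' @slot nStates number of azimuth states.
#' @slot resolutionDeg degrees per state.
#' @slot stepRateHz chain sampling rate in Hz.
#' @slot kernelProfile unnormalized step-probability profile over steps
#'   `-stepSpan:stepSpan` (odd length, symmetric by default).
#' @slot seed integer seed.
#' @export
setClass("MarkovChainConfig",
  representation(nStates = "integer", resolutionDeg = "numeric",
                 stepRateHz = "numeric", kernelProfile = "numeric",
                 seed = "integer"))

setValidity("MarkovChainConfig", function(object) {
  msg <- character()
  span <- (object@nStates - 1L) * object@resolutionDeg
  if (abs(span - 180) > 1e-9)
    msg <- c(msg, "nStates and resolutionDeg must span 180 degrees")
  if (length(object@kernelProfile) %% 2 != 1)
    msg <- c(msg, "kernelProfile must have odd length (centered on step 0)")
  if (any(object@kernelProfile < 0) || sum(object@kernelProfile) <= 0)
    msg <- c(msg, "kernelProfile must be nonnegative and normalizable")
  if (object@stepRateHz <= 0) msg <- c(msg, "stepRateHz must be positive")
  if (length(msg)) msg else TRUE
})

#' BinauralSignal: a stereo waveform
#'
#' @slot left,right numeric waveforms of equal length.
#' @slot fsHz sampling rate.
#' @export
setClass("BinauralSignal",
  representation(left = "numeric", right = "numeric", fsHz = "numeric"))

setValidity("BinauralSignal", function(object) {
  if (length(object@left) != length(object@right))
    return("left and right channels must have equal length")
  if (object@fsHz <= 0) return("fsHz must be positive")
  TRUE
})

#' ConversationScript: word timing, talker turns and repeat events
#'
#' @slot words data.frame with columns `onset_s`, `offset_s`, `talker`,
#'   `is_repeat_source`, `is_repeat_copy`.
#' @slot switchTimesS talker-switch times in seconds.
#' @slot repeatEvents data.frame with `onset_s`, `duration_s`, `stream`.
#' @slot streamId which conversation stream (1 = cued, 2 = uncued).
#' @export
setClass("ConversationScript",
  representation(words = "data.frame", switchTimesS = "numeric",
                 repeatEvents = "data.frame", streamId = "integer"))

setValidity("ConversationScript", function(object) {
  w <- object@words
  if (nrow(w) > 1 && any(diff(w$onset_s) < 0))
    return("words must be sorted by onset")
  if (nrow(w) && any(w$offset_s < w$onset_s))
    return("word offsets must not precede onsets")
  re <- object@repeatEvents
  if (nrow(re) > 1 && any(diff(re$onset_s) <= 0))
    return("repeat events must be strictly sorted by onset")
  TRUE
})

#' TrialScene: the full acoustic scene of one trial
#'
#' The mixture is the sample-wise sum of the two spatialized conversation
#' streams and the diotic background noise (y = s1 + s2 + n). The two
#' conversation streams have equal RMS over their active supports and the
#' noise power sits `noiseLevelDb` below a conversation stream.
#'
#' @slot mixture,conv1,conv2,noise [BinauralSignal-class] components.
#' @slot trajectories [TrajectoryPair-class] paths of the two conversations.
#' @slot scripts list of two [ConversationScript-class] objects.
#' @slot noiseLevelDb noise suppression in dB (-9 or -12).
#' @slot uncuedDelayS onset lag of the uncued conversation (3 s).
#' @slot meta list of generation metadata (seeds, gains, duration).
#' @export
setClass("TrialScene",
  representation(mixture = "BinauralSignal", conv1 = "BinauralSignal",
                 conv2 = "BinauralSignal", noise = "BinauralSignal",
                 trajectories = "TrajectoryPair", scripts = "list",
                 noiseLevelDb = "numeric", uncuedDelayS = "numeric",
                 meta = "list"))

setValidity("TrialScene", function(object) {
  n <- length(object@mixture@left)
  comps <- list(object@conv1, object@conv2, object@noise)
  if (any(vapply(comps, function(b) length(b@left), 0L) != n))
    return("all components must have the mixture's length")
  resid <- max(abs(object@mixture@left -
                   (object@conv1@left + object@conv2@left + object@noise@left)),
               abs(object@mixture@right -
                   (object@conv1@right + object@conv2@right + object@noise@right)))
  if (resid > 1e-6 * max(abs(object@mixture@left), 1e-12))
    return("mixture must equal conv1 + conv2 + noise")
  if (max(abs(object@noise@left - object@noise@right)) > 0)
    return("background noise must be diotic (identical channels)")
  TRUE
})

#' NeuralRecording: raw multichannel neural data
#'
#' @slot data channels x time matrix (microvolts).
#' @slot fsHz sampling rate.
#' @slot channelLabels character identifiers, one per row.
#' @export
setClass("NeuralRecording",
  representation(data = "matrix", fsHz = "numeric",
                 channelLabels = "character"))

setValidity("NeuralRecording", function(object) {
  if (object@fsHz <= 0) return("fsHz must be positive")
  if (any(!is.finite(object@data))) return("data must contain no NaN/Inf")
  if (length(object@channelLabels) &&
      length(object@channelLabels) != nrow(object@data))
    return("channelLabels must match the number of rows")
  TRUE
})

#' HighGammaEnvelope: 100 Hz high-gamma band envelopes
#'
#' @slot env channels x time matrix, nonnegative.
#' @slot fsHz exactly 100.
#' @slot bandEdges two-column matrix of sub-band (lo, hi) edges in Hz.
#' @export
setClass("HighGammaEnvelope",
  representation(env = "matrix", fsHz = "numeric", bandEdges = "matrix"))

setValidity("HighGammaEnvelope", function(object) {
  if (abs(object@fsHz - 100) > 1e-9) return("envelope rate must be 100 Hz")
  if (any(object@env < -1e-12)) return("envelopes must be nonnegative")
  TRUE
})

#' ElectrodeSelection: speech-responsiveness test result
#'
#' @slot tStats per-channel two-sample t statistic (speech vs silence).
#' @slot selected logical mask, `tStats > threshold`.
#' @slot threshold selection threshold (5).
#' @export
setClass("ElectrodeSelection",
  representation(tStats = "numeric", selected = "logical",
                 threshold = "numeric"))

setValidity("ElectrodeSelection", function(object) {
  if (!identical(unname(object@selected),
                 unname(object@tStats > object@threshold)))
    return("selected must equal tStats > threshold")
  TRUE
})

#' ForwardModel: linear stimulus-to-envelope generative model
#'
#' Synthetic high-gamma envelopes are the convolution of the attended
#' stream's features with smooth per-channel kernels over 0-500 ms lags,
#' plus a weaker unattended contribution and additive noise.
#'
#' @slot spectroKernels channels x melBins x lags array.
#' @slot trajKernels channels x lags matrix.
#' @slot unattendedGain scalar in \[0, 1).
#' @slot noiseSd noise standard deviation relative to the SD of the
#'   noiseless signal component (1 = 0 dB feature SNR; 0 = noiseless).
#' @slot seed integer seed used to draw the kernels.
#' @export
setClass("ForwardModel",
  representation(spectroKernels = "array", trajKernels = "matrix",
                 unattendedGain = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("ForwardModel", function(object) {
  if (object@unattendedGain < 0 || object@unattendedGain > 1)
    return("unattendedGain must be in [0, 1]")
  if (dim(object@spectroKernels)[3] > 50)
    return("kernel lag span must not exceed 500 ms (50 lags at 100 Hz)")
  if (nrow(object@trajKernels) != dim(object@spectroKernels)[1])
    return("trajKernels and spectroKernels must agree on channel count")
  TRUE
})

#' AttentionLabels: which stream is attended, moment to moment
#'
#' @slot attendedStream integer vector of stream ids (1 or 2) at `rateHz`.
#' @slot lapseIntervals two-column matrix of (start_s, end_s) lapses.
#' @slot rateHz label rate (100 Hz).
#' @export
setClass("AttentionLabels",
  representation(attendedStream = "integer", lapseIntervals = "matrix",
                 rateHz = "numeric"))

setValidity("AttentionLabels", function(object) {
  if (length(object@attendedStream) &&
      !all(object@attendedStream %in% c(1L, 2L)))
    return("attendedStream must contain stream ids 1 or 2")
  TRUE
})

#' ButtonPresses: behavioral response times
#'
#' @slot pressTimesS strictly increasing press times in seconds.
#' @export
setClass("ButtonPresses", representation(pressTimesS = "numeric"))

setValidity("ButtonPresses", function(object) {
  if (length(object@pressTimesS) > 1 && any(diff(object@pressTimesS) <= 0))
    return("press times must be strictly increasing")
  TRUE
})

#' StimFeatures: decoder-side stimulus representation of one stream
#'
#' @slot mel 40 x frames matrix (20 mel bins x left/right concatenated),
#'   100 Hz frame rate.
#' @slot traj 1 x frames matrix of azimuth, 100 Hz.
#' @slot rateHz frame rate (100).
#' @slot streamId stream identity.
#' @slot normalized logical; whether pooled-training normalization has
#'   been applied.
#' @export
setClass("StimFeatures",
  representation(mel = "matrix", traj = "matrix", rateHz = "numeric",
                 streamId = "integer", normalized = "logical"),
  prototype(normalized = FALSE))

setValidity("StimFeatures", function(object) {
  if (ncol(object@mel) != ncol(object@traj))
    return("mel and traj must be frame-aligned")
  TRUE
})

#' CCAModel: fitted trajectory-augmented CCA attention decoder
#'
#' Stores the full transform pipeline: pooled-training normalization
#' statistics, lag-embedding spans, per-block PCA bases retaining >= 95%
#' variance, and the paired CCA projections.
#'
#' @slot neuralLags,stimLags receptive-field lengths in frames (50, 20).
#' @slot normalizer list of pooled normalization statistics.
#' @slot pcaNeural,pcaMel,pcaTraj PCA bases (list: mean, rotation, varFrac).
#' @slot wNeural,wStim CCA projection matrices (columns = components).
#' @slot canCors training canonical correlations, descending.
#' @slot nVoteComponents components used for voting (3).
#' @slot useTrajectory logical; whether trajectory features were fused.
#' @slot meta training metadata (trial ids, frame counts).
#' @export
setClass("CCAModel",
  representation(neuralLags = "integer", stimLags = "integer",
                 normalizer = "list", pcaNeural = "list", pcaMel = "list",
                 pcaTraj = "list", wNeural = "matrix", wStim = "matrix",
                 canCors = "numeric", nVoteComponents = "integer",
                 useTrajectory = "logical", meta = "list"))

setValidity("CCAModel", function(object) {
  if (length(object@canCors) > 1 && any(diff(object@canCors) > 1e-8))
    return("canonical correlations must be sorted descending")
  TRUE
})

#' DecodingResult: windowed decoder output for one trial
#'
#' @slot windows data.frame with one row per window: `start_s`, `end_s`,
#'   correlations `corr1_1..3`, `corr2_1..3`, `votes_for_1`, `winner`,
#'   `label`, `cpi`.
#' @slot windowSizeS window size in seconds.
#' @slot accuracy fraction of windows whose winner matches the label.
#' @export
setClass("DecodingResult",
  representation(windows = "data.frame", windowSizeS = "numeric",
                 accuracy = "numeric"))

setValidity("DecodingResult", function(object) {
  w <- object@windows
  if (nrow(w) && !all(w$votes_for_1 %in% 0:3))
    return("votes_for_1 must be in 0..3")
  if (nrow(w) && any(abs(w$cpi - (w$votes_for_1 / 3 - 0.5)) > 1e-9))
    return("cpi must equal votes/3 - 0.5")
  TRUE
})

#' GainSolution: enhancement gains for the attended-stream remix
#'
#' Closed-form solution of the remix constraints: the attended stream's
#' total gain is exactly 1 and the attended-to-unattended gain ratio is
#' `suppressionDb` decibels.
#'
#' @slot k mixture gain.
#' @slot alphaAttended additive gain on the attended separated stream.
#' @slot alphaUnattended additive gain on the unattended stream (0).
#' @slot suppressionDb target suppression in dB.
#' @export
setClass("GainSolution",
  representation(k = "numeric", alphaAttended = "numeric",
                 alphaUnattended = "numeric", suppressionDb = "numeric"))

setValidity("GainSolution", function(object) {
  gA <- object@k + object@alphaAttended
  gU <- object@k + object@alphaUnattended
  if (abs(gA - 1) > 1e-9) return("attended total gain must be exactly 1")
  if (abs(20 * log10(gA / gU) - object@suppressionDb) > 1e-9)
    return("gain ratio must match suppressionDb")
  TRUE
})

#' SeparatedSources: surrogate output of the binaural separation model
#'
#' @slot streams list of two [BinauralSignal-class] estimates.
#' @slot estTrajectories list of two [Trajectory-class] estimates at
#'   12.5 Hz (80 ms localizer frames).
#' @slot fidelityMeta list of injected SNR-improvement / DOA-noise settings.
#' @export
setClass("SeparatedSources",
  representation(streams = "list", estTrajectories = "list",
                 fidelityMeta = "list"))

setValidity("SeparatedSources", function(object) {
  if (length(object@streams) != 2)
    return("exactly two separated streams are required")
  TRUE
})

#' StftPair: left/right complex spectrograms
#'
#' @slot yLeft,yRight complex F x H matrices.
#' @slot freqHz frequency axis.
#' @slot windowS,hopS analysis window and hop in seconds (0.032, 0.002).
#' @export
setClass("StftPair",
  representation(yLeft = "matrix", yRight = "matrix", freqHz = "numeric",
                 windowS = "numeric", hopS = "numeric"))

setValidity("StftPair", function(object) {
  if (!identical(dim(object@yLeft), dim(object@yRight)))
    return("left and right spectrograms must have matching shapes")
  TRUE
})

#' CrossDomainFeatures: interaural phase/level difference features
#'
#' @slot cosIpd,sinIpd,ild F x H real matrices.
#' @export
setClass("CrossDomainFeatures",
  representation(cosIpd = "matrix", sinIpd = "matrix", ild = "matrix"))

setValidity("CrossDomainFeatures", function(object) {
  if (!identical(dim(object@cosIpd), dim(object@sinIpd)) ||
      !identical(dim(object@cosIpd), dim(object@ild)))
    return("feature matrices must share a shape")
  u <- object@cosIpd^2 + object@sinIpd^2
  if (length(u) && max(abs(u - 1)) > 1e-6)
    return("cosIpd^2 + sinIpd^2 must equal 1")
  if (any(!is.finite(object@ild))) return("ild must be finite")
  TRUE
})

#' SeparatorArchSpec: dilated-TCN architecture description
#'
#' @slot nStacks repeated stacks (5).
#' @slot blocksPerStack convolutional blocks per stack (7).
#' @slot kernelSize 1-D convolution kernel size.
#' @slot dilationBase dilation growth factor per block (2).
#' @slot frameHopS encoder frame hop in seconds (0.002).
#' @export
setClass("SeparatorArchSpec",
  representation(nStacks = "integer", blocksPerStack = "integer",
                 kernelSize = "integer", dilationBase = "integer",
                 frameHopS = "numeric"))

setValidity("SeparatorArchSpec", function(object) {
  vals <- c(object@nStacks, object@blocksPerStack, object@kernelSize,
            object@dilationBase)
  if (any(vals < 1)) return("architecture fields must be positive integers")
  if (object@frameHopS <= 0) return("frameHopS must be positive")
  TRUE
})

#' BehaviorSummary: scored 1-back task performance
#'
#' @slot hitRate,faRate detection rates in \[0, 1\].
#' @slot dPrime sensitivity index.
#' @slot detections per-event detection table.
#' @export
setClass("BehaviorSummary",
  representation(hitRate = "numeric", faRate = "numeric", dPrime = "numeric",
                 detections = "data.frame"))

setValidity("BehaviorSummary", function(object) {
  if (object@hitRate < 0 || object@hitRate > 1 ||
      object@faRate < 0 || object@faRate > 1)
    return("rates must lie in [0, 1]")
  if (!is.finite(object@dPrime)) return("dPrime must be finite")
  TRUE
})
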