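# Decoder-side stimulus features: binaural 20-bin mel spectrograms at 100 Hz
# frames and the 100 Hz talker trajectory, with pooled-training
# normalization.

#' Compute stimulus features for one conversation stream
#'
#' 20-bin log-power mel spectrograms (30 ms window, 10 ms hop, audio
#' resampled to 16 kHz first) of the left and right channels concatenated
#' along the bin dimension (40 rows), plus the stream's azimuth trajectory
#' linearly upsampled to the 100 Hz frame rate. Features are returned
#' unnormalized; normalization statistics are fit on pooled training trials
#' with [fitFeatureNormalizer()] and applied with [applyFeatureNormalizer()].
#'
#' @param audio a [BinauralSignal-class] for the stream.
#' @param traj the stream's [Trajectory-class].
#' @param streamId stream identity (1 or 2).
#' @param nMel mel bins per channel (default 20).
#' @return a [StimFeatures-class].
#' @export
computeStimFeatures <- function(audio, traj, streamId = 1L, nMel = 20) {
  fs <- audio@fsHz
  l <- audio@left; r <- audio@right
  if (fs != 16000) {
    l <- resampleTo(l, fs, 16000); r <- resampleTo(r, fs, 16000)
    fs <- 16000
  }
  melL <- melSpectrogram(l, fs, nMel = nMel)
  melR <- melSpectrogram(r, fs, nMel = nMel)
  nF <- min(ncol(melL), ncol(melR))
  mel <- rbind(melL[, seq_len(nF), drop = FALSE],
               melR[, seq_len(nF), drop = FALSE])
  tf <- (seq_len(nF) - 1) / 100
  tr <- matrix(azimuthAt(traj, tf), 1, nF)
  new("StimFeatures", mel = mel, traj = tr, rateHz = 100,
      streamId = as.integer(streamId), normalized = FALSE)
}

#' Fit pooled feature-normalization statistics
#'
#' Mel bins are normalized bin-by-bin (zero mean, unit variance) and the
#' trajectory as a single series, over all frames of all supplied features
#' (training trials only; the held-out trial must not be included).
#'
#' @param featsList list of [StimFeatures-class] objects.
#' @return normalizer list (melMean, melSd, trajMean, trajSd).
#' @export
fitFeatureNormalizer <- function(featsList) {
  mel <- do.call(cbind, lapply(featsList, function(f) f@mel))
  tr <- do.call(cbind, lapply(featsList, function(f) f@traj))
  list(melMean = rowMeans(mel),
       melSd = pmax(apply(mel, 1, sd), 1e-9),
       trajMean = mean(tr), trajSd = max(sd(as.numeric(tr)), 1e-9))
}

#' Apply pooled normalization to stimulus features
#'
#' @param feats a [StimFeatures-class].
#' @param nrm output of [fitFeatureNormalizer()].
#' @return normalized [StimFeatures-class].
#' @export
applyFeatureNormalizer <- function(feats, nrm) {
  mel <- (feats@mel - nrm$melMean) / nrm$melSd
  tr <- (feats@traj - nrm$trajMean) / nrm$trajSd
  initialize(feats, mel = mel, traj = tr, normalized = TRUE)
}

#' Start-aligned time-lag embedding
#'
#' Row t of the output contains `X[, t .. t+nLags-1]` flattened (features
#' fastest within each lag block), so output rows = frames - nLags + 1.
#' Neural and stimulus embeddings share this starting-sample convention.
#'
#' @param X features x frames matrix (a vector is treated as 1 x frames).
#' @param nLags receptive-field length in frames.
#' @return (frames - nLags + 1) x (features * nLags) matrix.
#' @export
lagEmbed <- function(X, nLags) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  nF <- ncol(X)
  stopifnot(nF > nLags)
  nOut <- nF - nLags + 1
  do.call(cbind, lapply(seq_len(nLags), function(l)
    t(X[, l:(l + nOut - 1), drop = FALSE])))
}
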