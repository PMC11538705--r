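# Signal metrics: binaural STFT features, DOA error, chance levels and the
# dilated-TCN receptive-field arithmetic.

#' Left/right complex spectrograms of a binaural signal
#'
#' @param bs a [BinauralSignal-class].
#' @param windowS STFT window in seconds (default 0.032).
#' @param hopS hop in seconds (default 0.002).
#' @return an [StftPair-class].
#' @export
stftPair <- function(bs, windowS = 0.032, hopS = 0.002) {
  L <- stftComplex(bs@left, bs@fsHz, windowS, hopS)
  R <- stftComplex(bs@right, bs@fsHz, windowS, hopS)
  new("StftPair", yLeft = L$S, yRight = R$S, freqHz = L$freq,
      windowS = windowS, hopS = hopS)
}

#' Interaural phase and level difference features
#'
#' cosIPD = cos(angle(YL) - angle(YR)), sinIPD likewise, and
#' ILD = 10 log10(|YL| / |YR|) element-wise — note the 10 log10 magnitude
#' ratio (not the usual 20 log10 level-difference convention); magnitudes
#' are floored before the ratio.
#'
#' @param stft an [StftPair-class].
#' @param floor magnitude floor (default 1e-8).
#' @return a [CrossDomainFeatures-class].
#' @export
crossDomainFeatures <- function(stft, floor = 1e-8) {
  dphi <- Arg(stft@yLeft) - Arg(stft@yRight)
  magL <- pmax(Mod(stft@yLeft), floor)
  magR <- pmax(Mod(stft@yRight), floor)
  new("CrossDomainFeatures", cosIpd = cos(dphi), sinIpd = sin(dphi),
      ild = 10 * log10(magL / magR))
}

#' Mean absolute direction-of-arrival error
#'
#' Compares an estimated trajectory with the truth on 80 ms localizer
#' frames over their overlapping support.
#'
#' @param est,truth [Trajectory-class] objects.
#' @param frameS frame length in seconds (default 0.08).
#' @return mean absolute azimuth error in degrees.
#' @export
doaError <- function(est, truth, frameS = 0.08) {
  t0 <- max(est@t0S, truth@t0S)
  t1 <- min(est@t0S + durationS(est), truth@t0S + durationS(truth))
  stopifnot(t1 > t0)
  tf <- seq(t0, t1 - frameS / 2, by = frameS)
  mean(abs(azimuthAt(est, tf) - azimuthAt(truth, tf)))
}

#' Chance-level DOA error by Monte Carlo
#'
#' Mean absolute difference of independent uniform azimuth pairs on
#' \[-90, 90\] (expectation 60 degrees).
#'
#' @param nSamples number of pairs (default 1e6).
#' @param seed integer seed.
#' @return mean absolute error in degrees.
#' @export
chanceDoaErrorDeg <- function(nSamples = 1e6, seed = 1L) {
  set.seed(seed)
  mean(abs(runif(nSamples, -90, 90) - runif(nSamples, -90, 90)))
}

#' Chance accuracy of sector localization
#'
#' @param nSectors equally partitioned frontal sectors (default 5).
#' @return chance accuracy in percent (20 for 5 sectors).
#' @export
chanceSectorAccuracy <- function(nSectors = 5L) 100 / nSectors

#' Construct a dilated-TCN architecture description
#'
#' @param nStacks repeated stacks (default 5).
#' @param blocksPerStack 1-D convolutional blocks per stack (default 7).
#' @param kernelSize convolution kernel size (default 3).
#' @param dilationBase dilation growth per block (default 2).
#' @param frameHopS encoder frame hop in seconds (default 0.002).
#' @return a [SeparatorArchSpec-class].
#' @export
separatorArchSpec <- function(nStacks = 5L, blocksPerStack = 7L,
                              kernelSize = 3L, dilationBase = 2L,
                              frameHopS = 0.002) {
  new("SeparatorArchSpec", nStacks = as.integer(nStacks),
      blocksPerStack = as.integer(blocksPerStack),
      kernelSize = as.integer(kernelSize),
      dilationBase = as.integer(dilationBase), frameHopS = frameHopS)
}

#' Effective receptive field of the dilated-TCN stack
#'
#' frames = 1 + nStacks * sum_{b=0}^{blocks-1} (kernel - 1) * base^b;
#' seconds = frames * frameHop. The default architecture gives ~2.5 s.
#'
#' @param spec a [SeparatorArchSpec-class].
#' @return receptive field in seconds.
#' @export
receptiveFieldSeconds <- function(spec = separatorArchSpec()) {
  validObject(spec)
  perStack <- sum((spec@kernelSize - 1) *
                    spec@dilationBase^(0:(spec@blocksPerStack - 1)))
  (1 + spec@nStacks * perStack) * spec@frameHopS
}
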