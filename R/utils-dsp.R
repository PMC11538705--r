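#' @import methods
#' @importFrom stats approx rnorm runif rpois rexp qnorm sd cor var fft
#'   convolve quantile t.test rbinom median
#' @importFrom utils head tail write.csv read.csv
NULL

# Internal DSP helpers shared across modules. These are deliberately small:
# filtering/resampling goes through the 'signal' package; only primitives with
# no installed provider (analytic signal, mel filterbank, pink noise) are local.

#' Analytic signal via the frequency-domain construction
#'
#' Returns the complex analytic signal whose modulus is the amplitude
#' envelope (the magnitude of the Hilbert-transform pair).
#'
#' @param x numeric vector.
#' @return complex vector, same length as `x`.
#' @keywords internal
analyticSignal <- function(x) {
  n0 <- length(x)
  # pad to a 2/3/5-smooth length: R's mixed-radix FFT degrades to
  # near-quadratic cost on lengths with large prime factors
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) x <- c(x, numeric(n - n0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  (fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' Amplitude envelope of a real signal
#' @keywords internal
amplitudeEnvelope <- function(x) Mod(analyticSignal(x))

# Rate conversion: zero-phase FIR anti-aliasing (when decimating) followed
# by linear interpolation onto the target grid. Unit passband gain.
resampleTo <- function(x, fsIn, fsOut) {
  if (fsIn == fsOut) return(x)
  if (fsOut < fsIn) {
    ord <- min(400L, max(40L, 8L * ceiling(fsIn / fsOut)))
    b <- signal::fir1(ord, 0.9 * fsOut / fsIn)
    x <- signal::filtfilt(b, x)
  }
  tIn <- (seq_along(x) - 1) / fsIn
  nOut <- round(length(x) * fsOut / fsIn)
  approx(tIn, x, xout = (seq_len(nOut) - 1) / fsOut, rule = 2)$y
}

# Resample every row of a channels x time matrix.
resampleRows <- function(mat, fsIn, fsOut) {
  out <- t(apply(mat, 1, resampleTo, fsIn = fsIn, fsOut = fsOut))
  if (nrow(mat) == 1) out <- matrix(out, nrow = 1)
  out
}

#' Pink (1/f) noise
#'
#' Spectral-domain synthesis: white Gaussian spectrum shaped by 1/sqrt(f),
#' unit-variance output. Used by the pedestrian background-noise surrogate.
#' @keywords internal
pinkNoise <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- stats::nextn(n, c(2, 3, 5))   # smooth FFT length
  X <- fft(rnorm(m))
  f <- c(1, seq_len(m - 1))
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE) / m)[seq_len(n)]
  (x - mean(x)) / sd(x)
}

# Raised-cosine (Hann) ramps applied in place to both edges of a segment.
applyRamps <- function(x, fs, rampS) {
  nr <- min(round(rampS * fs), floor(length(x) / 2))
  if (nr < 1) return(x)
  w <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
  x[seq_len(nr)] <- x[seq_len(nr)] * w
  x[(length(x) - nr + 1):length(x)] <- x[(length(x) - nr + 1):length(x)] * rev(w)
  x
}

rmsLevel <- function(x) sqrt(mean(x^2))

db <- function(p) 10 * log10(p)

# ---- STFT / mel front end -------------------------------------------------

# Complex STFT via signal::specgram. Returns bins x frames complex matrix plus
# the frequency axis. Window is a Hann of `winSamp` samples, hop `hopSamp`.
stftComplex <- function(x, fs, winS, hopS) {
  winSamp <- round(winS * fs)
  hopSamp <- round(hopS * fs)
  sg <- signal::specgram(x, n = winSamp, Fs = fs, window = winSamp,
                         overlap = winSamp - hopSamp)
  list(S = sg$S, freq = as.numeric(sg$f), t = as.numeric(sg$t),
       winSamp = winSamp, hopSamp = hopSamp)
}

hzToMel <- function(f) 2595 * log10(1 + f / 700)
melToHz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular HTK-style mel filterbank: nMel x nBins weights.
melFilterbank <- function(nMel, freq, fMin = 50, fMax = NULL) {
  if (is.null(fMax)) fMax <- max(freq)
  edges <- melToHz(seq(hzToMel(fMin), hzToMel(fMax), length.out = nMel + 2))
  fb <- matrix(0, nMel, length(freq))
  for (m in seq_len(nMel)) {
    lo <- edges[m]; cen <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freq - lo) / (cen - lo)
    down <- (hi - freq) / (hi - cen)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Log-power mel spectrogram: nMel x frames.
melSpectrogram <- function(x, fs, nMel = 20, winS = 0.030, hopS = 0.010,
                           fMin = 50, floorDb = -80) {
  st <- stftComplex(x, fs, winS, hopS)
  p <- Mod(st$S)^2
  fb <- melFilterbank(nMel, st$freq, fMin = fMin)
  m <- fb %*% p
  ref <- max(m, 1e-12)
  lm <- 10 * log10(pmax(m / ref, 10^(floorDb / 10)))
  lm
}

# Frame count of the 30/10 ms analysis applied to n samples at rate fs.
melFrameCount <- function(nSamples, fs, winS = 0.030, hopS = 0.010) {
  floor((nSamples - round(winS * fs)) / round(hopS * fs)) + 1
}

# Linear interpolation of a series onto a new time grid (rule 2 at edges).
interpSeries <- function(t, y, tOut) {
  approx(t, y, xout = tOut, rule = 2)$y
}
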