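# Markov-chain azimuth trajectories and the pair criteria used to build a
# trial's two moving conversations.

#' Construct a Markov-chain trajectory configuration
#'
#' The chain walks on a 1-degree azimuth grid spanning the frontal half
#' plane (181 states from -90 to +90 degrees) at 0.5 Hz. The transition
#' kernel is a local random-walk profile: unnormalized probabilities over
#' steps `-stepSpan .. +stepSpan` grid states, by default a symmetric
#' triangular profile over +/-3 states, renormalized per row (mass falling
#' outside the grid at the edges is dropped before renormalization).
#'
#' @param resolutionDeg grid resolution in degrees (default 1).
#' @param stepRateHz chain sampling rate in Hz (default 0.5).
#' @param stepSpan maximum step magnitude in grid states (default 3).
#' @param kernelProfile optional explicit unnormalized profile over steps
#'   `-stepSpan:stepSpan`; overrides the triangular default.
#' @param seed integer seed.
#' @return a [MarkovChainConfig-class].
#' @export
markovChainConfig <- function(resolutionDeg = 1, stepRateHz = 0.5,
                              stepSpan = 3, kernelProfile = NULL,
                              seed = 1L) {
  nStates <- as.integer(round(180 / resolutionDeg)) + 1L
  if (is.null(kernelProfile))
    kernelProfile <- (stepSpan + 1) - abs(seq(-stepSpan, stepSpan))
  new("MarkovChainConfig", nStates = nStates, resolutionDeg = resolutionDeg,
      stepRateHz = stepRateHz, kernelProfile = as.numeric(kernelProfile),
      seed = as.integer(seed))
}

#' Number of azimuth states of a chain configuration
#' @param cfg a [MarkovChainConfig-class].
#' @return integer state count (181 at 1-degree resolution).
#' @export
markovStateCount <- function(cfg) cfg@nStates

#' Full transition matrix of a chain configuration
#'
#' Rows are current states, columns next states; each row sums to 1.
#' @param cfg a [MarkovChainConfig-class].
#' @return nStates x nStates matrix.
#' @export
transitionMatrix <- function(cfg) {
  n <- cfg@nStates
  span <- (length(cfg@kernelProfile) - 1L) %/% 2L
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- i + seq(-span, span)
    keep <- js >= 1 & js <= n
    P[i, js[keep]] <- cfg@kernelProfile[keep]
    P[i, ] <- P[i, ] / sum(P[i, ])
  }
  if (any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition kernel rows are not normalizable")
  P
}

#' Generate a raw Markov-chain trajectory
#'
#' Draws `nSteps` azimuth samples at the chain rate. The initial state is
#' uniform over all states unless `startStateDeg` pins it.
#'
#' @param cfg a [MarkovChainConfig-class].
#' @param nSteps number of samples (>= 2).
#' @param seed integer seed (defaults to `cfg@seed`).
#' @param startStateDeg optional fixed starting azimuth in degrees.
#' @return a [Trajectory-class] at the chain rate, on the state grid.
#' @export
generateMarkovTrajectory <- function(cfg, nSteps, seed = cfg@seed,
                                     startStateDeg = NULL) {
  stopifnot(nSteps >= 2)
  validObject(cfg)
  if (sum(cfg@kernelProfile) <= 0)
    stop("invalid transition kernel: rows not normalizable")
  n <- cfg@nStates
  span <- (length(cfg@kernelProfile) - 1L) %/% 2L
  set.seed(seed)
  state <- if (is.null(startStateDeg)) {
    sample.int(n, 1)
  } else {
    as.integer(round((startStateDeg + 90) / cfg@resolutionDeg)) + 1L
  }
  states <- integer(nSteps)
  states[1] <- state
  steps <- seq(-span, span)
  for (t in 2:nSteps) {
    js <- state + steps
    keep <- js >= 1 & js <= n
    p <- cfg@kernelProfile[keep]
    state <- js[keep][sample.int(sum(keep), 1, prob = p)]
    states[t] <- state
  }
  new("Trajectory", azimuthDeg = (states - 1L) * cfg@resolutionDeg - 90,
      rateHz = cfg@stepRateHz, t0S = 0)
}

#' Smooth, stretch and upsample a raw trajectory
#'
#' Applies a centered moving average of `smoothWindow` samples, affinely
#' stretches the result to span the full frontal half plane (min -90, max
#' +90), and linearly interpolates to `targetRateHz`. A constant input
#' cannot be stretched; it is returned unstretched with a warning.
#'
#' @param traj a [Trajectory-class].
#' @param smoothWindow moving-average length in samples (default 5).
#' @param targetRateHz output rate (default 10).
#' @return a [Trajectory-class] at `targetRateHz`.
#' @export
smoothStretchUpsample <- function(traj, smoothWindow = 5, targetRateHz = 10) {
  stopifnot(smoothWindow >= 1, targetRateHz >= traj@rateHz)
  a <- traj@azimuthDeg
  if (smoothWindow > 1 && length(a) >= smoothWindow) {
    k <- rep(1 / smoothWindow, smoothWindow)
    sm <- as.numeric(stats::filter(a, k, sides = 2))
    # centered moving average leaves NA at the edges; shrink the window there
    half <- (smoothWindow - 1) %/% 2
    for (i in which(is.na(sm))) {
      lo <- max(1, i - half); hi <- min(length(a), i + half)
      sm[i] <- mean(a[lo:hi])
    }
    a <- sm
  }
  rng <- range(a)
  if (diff(rng) < 1e-9) {
    warning("constant trajectory: stretch skipped")
  } else {
    a <- (a - rng[1]) / diff(rng) * 180 - 90
  }
  tIn <- traj@t0S + (seq_along(a) - 1) / traj@rateHz
  dur <- length(a) / traj@rateHz
  tOut <- traj@t0S + seq(0, dur - 1 / targetRateHz, by = 1 / targetRateHz)
  out <- interpSeries(tIn, a, tOut)
  new("Trajectory", azimuthDeg = out, rateHz = targetRateHz, t0S = traj@t0S)
}

#' Check the three trajectory-pair criteria
#'
#' A valid pair must have (i) spatial separation of at least 90 degrees
#' when the uncued conversation starts, (ii) at least 45 degrees at the
#' attended talker switch, and (iii) Pearson correlation below 0.5. The
#' correlation of constant trajectories is defined as 0.
#'
#' @param pair a [TrajectoryPair-class].
#' @param uncuedOnsetS onset time of the uncued conversation (seconds).
#' @param attendedSwitchS attended talker-switch time (seconds).
#' @return the pair with `criteriaReport` filled: columns `criterion`,
#'   `measured`, `required`, `pass`.
#' @export
checkPairCriteria <- function(pair, uncuedOnsetS, attendedSwitchS) {
  a <- pair@trajA; b <- pair@trajB
  tMax <- min(durationS(a) + a@t0S, durationS(b) + b@t0S)
  tMin <- max(a@t0S, b@t0S)
  if (uncuedOnsetS < tMin - 1e-9 || uncuedOnsetS > tMax + 1e-9 ||
      attendedSwitchS < tMin - 1e-9 || attendedSwitchS > tMax + 1e-9)
    stop("test time outside trajectory support")
  sepOnset <- abs(azimuthAt(a, uncuedOnsetS) - azimuthAt(b, uncuedOnsetS))
  sepSwitch <- abs(azimuthAt(a, attendedSwitchS) - azimuthAt(b, attendedSwitchS))
  nn <- min(length(a@azimuthDeg), length(b@azimuthDeg))
  xa <- a@azimuthDeg[seq_len(nn)]; xb <- b@azimuthDeg[seq_len(nn)]
  r <- if (sd(xa) < 1e-12 || sd(xb) < 1e-12) 0 else cor(xa, xb)
  rep <- data.frame(
    criterion = c("separation_at_uncued_onset_deg",
                  "separation_at_attended_switch_deg",
                  "pearson_correlation"),
    measured = c(sepOnset, sepSwitch, r),
    required = c(">=90", ">=45", "<0.5"),
    pass = c(sepOnset >= 90, sepSwitch >= 45, r < 0.5),
    stringsAsFactors = FALSE)
  rep <- rbind(rep, data.frame(criterion = "overall", measured = NA_real_,
                               required = "all", pass = all(rep$pass)))
  initialize(pair, criteriaReport = rep)
}

#' Joint entropy of a set of trajectory pairs
#'
#' Pools all (azimuth A, azimuth B) sample pairs of a set into a 2-D
#' histogram with `binDeg`-degree bins and returns the Shannon entropy in
#' bits.
#'
#' @param pairs list of [TrajectoryPair-class] objects.
#' @param binDeg histogram bin size in degrees (default 20; must divide 180).
#' @return joint entropy in bits.
#' @export
jointEntropyBits <- function(pairs, binDeg = 20) {
  stopifnot(length(pairs) > 0, abs(180 / binDeg - round(180 / binDeg)) < 1e-9)
  nBins <- as.integer(round(180 / binDeg))
  brk <- seq(-90, 90, by = binDeg)
  counts <- matrix(0, nBins, nBins)
  for (p in pairs) {
    nn <- min(length(p@trajA@azimuthDeg), length(p@trajB@azimuthDeg))
    ia <- pmin(nBins, pmax(1L, findInterval(p@trajA@azimuthDeg[seq_len(nn)],
                                            brk, rightmost.closed = TRUE)))
    ib <- pmin(nBins, pmax(1L, findInterval(p@trajB@azimuthDeg[seq_len(nn)],
                                            brk, rightmost.closed = TRUE)))
    for (k in seq_len(nn)) counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1
  }
  pr <- counts / sum(counts)
  pr <- pr[pr > 0]
  -sum(pr * log2(pr))
}

#' Select the trajectory-pair set with the highest joint entropy
#'
#' @param candidateSets list of sets, each a non-empty list of
#'   [TrajectoryPair-class] objects.
#' @param binDeg histogram bin size in degrees (default 20).
#' @return index of the selected set (ties broken by lowest index).
#' @export
selectMaxEntropySet <- function(candidateSets, binDeg = 20) {
  if (length(candidateSets) == 0) stop("empty candidate list")
  ent <- vapply(candidateSets, jointEntropyBits, 0, binDeg = binDeg)
  which.max(ent) # which.max breaks ties by lowest index
}

#' Generate one criteria-passing trajectory pair
#'
#' Draws raw Markov-chain trajectories, smooths/stretches/upsamples them to
#' 10 Hz, and retries until [checkPairCriteria()] passes.
#'
#' @param durationS trial duration in seconds.
#' @param uncuedOnsetS uncued conversation onset (default 3).
#' @param attendedSwitchS attended talker switch time (default mid-trial).
#' @param cfg a [MarkovChainConfig-class].
#' @param seed integer seed.
#' @param maxTries retry bound (default 500).
#' @return a [TrajectoryPair-class] with a passing `criteriaReport`.
#' @export
generateTrajectoryPair <- function(durationS, uncuedOnsetS = 3,
                                   attendedSwitchS = durationS / 2,
                                   cfg = markovChainConfig(), seed = 1L,
                                   maxTries = 500L) {
  nSteps <- ceiling(durationS * cfg@stepRateHz) + 1L
  for (i in seq_len(maxTries)) {
    sA <- seed * 10000L + 2L * i
    tA <- smoothStretchUpsample(generateMarkovTrajectory(cfg, nSteps, seed = sA))
    tB <- smoothStretchUpsample(generateMarkovTrajectory(cfg, nSteps, seed = sA + 1L))
    pair <- checkPairCriteria(new("TrajectoryPair", trajA = tA, trajB = tB),
                              uncuedOnsetS, attendedSwitchS)
    if (pair@criteriaReport$pass[4]) return(pair)
  }
  stop("no criteria-passing trajectory pair found within maxTries")
}
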