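# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# One audited trial scene (fixed duration for speed and reproducibility).
fixtureScene <- function() cached("scene", buildTrialScene(seed = 2L, durationS = 40))

# Small noiseless experiment: exact linear stimulus-to-envelope map.
fixtureNoiselessExp <- function() cached("noiseless", {
  fm <- forwardModel(nChannels = 12L, unattendedGain = 0, noiseSd = 0,
                     seed = 11L)
  simulateExperiment(3, fm = fm, durationS = 36, seed = 21L)
})

# Study-scale experiment at the default (calibrated) noise level.
fixtureStudyExp <- function() cached("study", {
  fm <- forwardModel(nChannels = 16L, seed = 11L)
  simulateExperiment(8, fm = fm, durationS = 36, seed = 4L)
})

fixtureStudyLoto <- function() cached("studyLoto", {
  lotoDecode(fixtureStudyExp(), windowSizesS = c(0.5, 1, 2, 4, 8, 16, 32),
             labelPolicy = "cued")
})

constTrajectory <- function(azimuth, n = 500, rateHz = 10, t0S = 0)
  new("Trajectory", azimuthDeg = rep(azimuth, n), rateHz = rateHz, t0S = t0S)

pairOf <- function(a, b, rateHz = 10)
  new("TrajectoryPair",
      trajA = new("Trajectory", azimuthDeg = a, rateHz = rateHz),
      trajB = new("Trajectory", azimuthDeg = b, rateHz = rateHz))
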