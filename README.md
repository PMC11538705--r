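# cocktailAAD

Auditory attention decoding (AAD) asks which of several concurrent speech
streams a listener is following, directly from neural activity — the core
of a brain-controlled hearing device that could selectively enhance the
attended talker. Most AAD work uses static scenes; `cocktailAAD` targets
the harder, realistic setting of **two spatially moving conversations**
with turn-taking talkers in background noise, and implements the full
pipeline at desk scale in R:

* **Scene simulation** — azimuth trajectories from a first-order Markov
  chain on a 1° grid (181 states, 0.5 Hz, smoothed/stretched/upsampled to
  10 Hz) with pair criteria (≥90° separation at uncued onset, ≥45° at the
  attended talker switch, correlation < 0.5); two turn-taking synthetic
  conversations with repeated words inserted for a 1-back attention probe
  under nine timing criteria; a Woodworth spherical-head ITD/ILD binaural
  renderer; diotic pedestrian/babble noise 9 or 12 dB below a stream.
* **Neural preprocessing** — resample → common average reference → 400 Hz
  → zero-phase FIR notch (60/120/180 Hz) → eight 10 Hz-wide band-passes
  spanning 70–150 Hz → analytic-signal envelopes → mean envelope at
  100 Hz; speech-responsive electrode selection by two-sample t > 5.
* **Synthetic neural generator** — 100 Hz high-gamma envelopes that
  linearly track the attended stream's mel spectrogram and trajectory over
  0–500 ms lags, with a weaker unattended contribution, additive noise and
  Poisson/exponential attention lapses; simulated button presses.
* **Attention decoder** — canonical correlation analysis (CCA) between
  lag-embedded neural data (500 ms receptive field) and lag-embedded
  stimulus features (200 ms; 40-row binaural 20-bin mel spectrogram +
  azimuth trajectory), PCA at 95% variance per block, voting by the first
  three canonical correlations, channel preference index
  CPI = votes/3 − 0.5, behavior correction by label swapping on
  press-bounded portions, leave-one-trial-out evaluation, transition-time
  analysis after simulated output swaps.
* **Enhancement & metrics** — closed-form remix gains
  (20·log10((k+α1)/(k+α2)) = 9 dB, k+α1 = 1, α2 = 0), an oracle separation
  surrogate with controllable SNR-improvement and DOA-error fidelity,
  SNR(x, x̂) = 10·log10‖x‖²/‖x−x̂‖², interaural phase/level features
  (ILD = 10·log10 magnitude ratio, per the source convention), chance
  levels (60° DOA, 20% sectors) and dilated-TCN receptive-field
  arithmetic (≈2.5 s).

The package is aimed at auditory-neuroscience and BCI researchers who want
a tested, fully synthetic sandbox for AAD methodology — every stage runs
without patient iEEG or GPU-trained separation networks.

## Worked example

```r
library(cocktailAAD)

scene <- buildTrialScene(seed = 42)
scene
#> TrialScene: 46.9 s at 16000 Hz, noise -9 dB, uncued lag 3 s, 14 repeats

audit <- auditTrialScene(scene)
sum(audit$pass)              # all 16 generation checks pass
#> [1] 16

# a small synthetic study: 4 trials, 16 channels, calibrated noise
fm  <- forwardModel(nChannels = 16, seed = 1)
exp <- simulateExperiment(4, fm = fm, durationS = 36, seed = 7)
res <- lotoDecode(exp, windowSizesS = c(1, 4, 16), labelPolicy = "corrected")
round(colMeans(res$accuracy), 3)
#>  win1  win4 win16
#> 0.714 0.906 1.000

res$models[[1]]
#> CCAModel: 7 canonical components (top r = 0.564), lags 50/20, spectrogram+trajectory

summarizeBehavior(exp$trials[[1]]$presses, exp$trials[[1]]$events)
#> BehaviorSummary: hit 0.600, FA 0.000, d' = 1.53

# enhance the attended conversation with ideal separation
sep <- oracleSeparate(scene)
enhancementAudit(scene, sep, attended = 1, gains = solveGains(9))
#> $suppressionDb          [1] 9        # attended 9 dB over unattended
#> $attendedPowerChangeDb  [1] 0        # attended power preserved
```

Decoding accuracy grows with window size (more evidence per decision);
the 9 dB figure is the designed power advantage of the attended
conversation in the remixed output, and the 0 dB change confirms the
attended stream keeps exactly its original mixture power.

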