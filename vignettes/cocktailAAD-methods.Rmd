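---
title: "Decoding attention to moving conversations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding attention to moving conversations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cocktailAAD)
```

# The problem

In a cocktail-party scene a listener follows one of several concurrent
conversations while the talkers move through space. A brain-controlled
hearing device must (i) separate the acoustic streams, (ii) decode from the
listener's neural activity which stream is attended, and (iii) re-render
the scene with the attended stream enhanced. `cocktailAAD` implements a
desk-scale, fully synthetic version of this pipeline for auditory attention
decoding (AAD) research: every stage is testable end to end without
patient intracranial recordings or GPU-trained separation networks.

# Acoustic scenes

## Trajectories

Each conversation moves along an azimuth path in the frontal half plane
(−90°, right, to +90°, left). Paths are drawn from a first-order Markov
chain on a 1° grid — 181 states — at 0.5 Hz, smoothed with a five-sample
moving average, affinely stretched to span the full half plane, and
linearly upsampled to 10 Hz. The chain's transition kernel is a local
random walk: probability mass on steps within ±K grid states (default a
symmetric triangular profile over ±3 states, exposed in
`markovChainConfig()`). A local smooth kernel preserves the two properties
that matter downstream — first-order dynamics and slow, continuous motion —
while keeping the step-profile an explicit, inspectable parameter.

A trial's two trajectories must satisfy three pair criteria: ≥90°
separation when the second (uncued) conversation starts, ≥45° separation at
the attended talker switch, and Pearson correlation < 0.5
(`checkPairCriteria()`). The correlation of constant trajectories is
defined as 0 (a variance-zero guard). Experiment-level designs can select
among candidate trajectory sets by joint entropy of the pooled 2-D azimuth
histogram with 20° bins (`selectMaxEntropySet()`); generating candidate
sets is exposed as an option rather than a default because a 1000-set
search adds nothing to desk-scale validation.

## Conversations and the 1-back task

Each trial holds two turn-taking conversations: the cued stream switches
talker at ~50% trial time, the uncued stream (starting 3 s late) at ~25%
and ~75%. Trial durations are drawn from Normal(44.2 s, SD 2.0 s)
truncated to [40, 50] s. Speech is synthesized (`synthSpeechlikeUtterance()`)
as amplitude-modulated harmonic-plus-noise words with formant-like spectral
peaks — a fixture-grade stand-in for voice actors that has word-level
timing, talker-specific spectra and realistic modulation statistics, but
no phonetic content.

Repeated words probe attention (press a button when a word repeats in the
followed conversation). The repeat scheduler (`planRepeatInsertion()`)
satisfies, per trial: round(duration/7) repeats per stream and equal counts
across streams; candidate words ≥300 ms; 30 ms Hann ramps on both edges of
the inserted copy and 200 ms silence padding on both sides; same-stream
inter-onset intervals within [5.5, 9.5] s; the first onset in [5, 8] s;
cross-stream onsets ≥2.5 s apart; and exactly one repeat within 1.5 s after
the attended talker switch. Because splice-insertion into a fixed recording
would shift every downstream onset while the criteria constrain the final
timeline, the scheduler samples repeat sites in final trial time first
(anchoring the post-switch repeat, growing the remaining onsets with
feasibility-bounded gaps, and placing the uncued stream's onsets in the
allowed union of intervals), then synthesis builds speech around the sites.
`auditTrialScene()` re-checks every criterion independently from the
finished scene.

## Spatialization and mixing

Binaural rendering uses a spherical-head surrogate: per-sample fractional
delays from the Woodworth ITD model, ITD(θ) = (a/c)(sin θ + θ) with head
radius a = 8.75 cm, plus a broadband level difference ILD(θ) =
ILDmax · sin θ (default 10 dB at ±90°). This preserves the cues the decoder
and separation contracts rely on — consistent, azimuth-dependent ITD/ILD —
without a binary HRTF SDK; `spatialize()` is the single hook to replace
with measured HRTFs. Background noise is diotic: pink noise with transient
bursts ("pedestrian") or a sum of eight synthetic utterance streams
("babble"), set 9 or 12 dB below a conversation stream's power. The two
conversation streams are equalized to the same RMS over their active
supports, and the mixture is exactly their sample-wise sum plus noise.

# Synthetic neural data

Real iEEG is unavailable, so `simulateNeural()` generates 100 Hz
high-gamma envelopes with exactly the structure the decoder assumes:

env(c, t) = Σ_f Σ_d K(c, f, d) · X_att(f, t−d)
           + g_u · [same for the unattended stream] + noise,

with kernels K over 0–500 ms lags (smooth Gaussian random fields,
~50 ms lag smoothness so filters are estimable from a handful of trials),
X the per-stream standardized log-mel features plus azimuth trajectory,
unattended gain g_u = 0.3, and i.i.d. Gaussian noise. The noise scale is
expressed relative to the SD of the noiseless signal component; the default
`noiseSd = 20` (−26 dB per-channel feature SNR) was chosen so the decoder's
accuracy-versus-window-size curve occupies the dynamic range reported for
intracranial AAD — roughly 70% at half-second windows rising toward ceiling
at tens of seconds — rather than saturating. Sixteen to thirty channels are
used (the per-subject speech-responsive electrode counts run 17–42).

Attention labels default to the cued stream with optional lapses: lapse
onsets form a Poisson process (rate per attended minute) with
exponentially distributed durations, an alternating-renewal process whose
uncued-time fraction has the closed form m/(m + 1/λ) used in the tests.
Button presses follow: hits with probability `pHit` and truncated-normal
reaction times for repeats in the currently attended stream, false alarms
with probability `pFa` otherwise.

What the generator does *not* emulate: non-linear and adaptive neural
responses, correlated (shared) noise across electrodes, non-stationarity,
artifacts, and any low-frequency (delta/alpha) attention signatures.
Passing tests therefore demonstrate the pipeline's correctness and its
qualitative directions under the linear model — not patient-level accuracy.

A broadband mode (`broadbandFromEnvelope()`) emits 400 Hz carriers (one
tone per 10 Hz sub-band) amplitude-modulated by the envelopes so the
preprocessing chain can be exercised end to end. Note that a 10 Hz-wide
filter bank can only track envelope content below ~5 Hz, so round-trip
fidelity is assessed on envelopes without fast additive noise.

# Preprocessing

`standardizeRecording()` resamples to 1000 Hz (zero-phase FIR anti-aliased),
subtracts the common average reference, downsamples to 400 Hz and removes
60/120/180 Hz line noise with a zero-phase order-1000 FIR notch.
`highGammaEnvelope()` filters through eight consecutive 10 Hz-wide
zero-phase FIR band-passes spanning 70–150 Hz (order 300, ≥40 dB
stopband; the filter family/order is a free design choice), takes the
magnitude of the analytic signal per sub-band, averages the eight
envelopes and resamples to exactly 100 Hz (clipped at zero against
resampler undershoot). Speech-responsive electrodes are selected by a
pooled-variance two-sample t test on 25 randomly drawn envelope samples
per trial from a silence window (−0.4 to −0.1 s around speech onset) and a
speech window (0.1 to 1.6 s), thresholded at t > 5; draws are seeded and
by default without replacement (both exposed).

# The attention decoder

Stimulus features are 20-bin log-power mel spectrograms (30 ms window,
10 ms hop, audio at 16 kHz) of the left and right channels concatenated
(40 rows) plus the azimuth trajectory at 100 Hz. Normalization statistics
(per mel bin; the trajectory as one series) are computed on pooled
*training* trials only and re-applied to test data.

The decoder lag-embeds both sides with start-aligned receptive fields —
500 ms (50 frames) for neural envelopes, 200 ms (20 frames) for stimulus
features — applies PCA per block retaining ≥95% variance, concatenates the
stimulus blocks (mel, then trajectory; concatenation of lagged-PCA blocks
is the fusion mechanism), and solves CCA via the whitened cross-covariance
SVD with a 1e−8 ridge on the covariance diagonals for numerical stability.
Covariances are accumulated trial by trial, so no stacked lag matrix is
ever materialized.

At test time the held-out trial is projected through the trained filters
for each candidate stream. In non-overlapping windows, each of the first
three canonical components votes for the stream with the higher projected
correlation; the winner is the majority (three voters, so no stream ties;
equal component correlations credit stream 1 and are flagged degenerate).
Per-window correlations are computed on the raw projected series, not
re-standardized per window. The channel preference index is
CPI = votes-for-stream-1 / 3 − 0.5. Continuous tracking uses a sliding 4 s
window with 100 ms steps (`slidingCpi()`), and `transitionTime()` reports
the first zero crossing of the trial-averaged CPI after a simulated output
swap, linearly interpolated between window centers (NA if it never
crosses).

Behavior correction: trials with ≥2 detected repeats in the uncued stream
have their attend/unattend labels swapped on the portion bounded by the
first and last such press (edges configurable) before training and
evaluation. Evaluation is leave-one-trial-out throughout; the held-out
trial contributes nothing to normalization, PCA or CCA — a property the
test suite checks by perturbing the held-out trial and asserting the
fitted model is bit-identical.

# Enhancement and evaluation

With the attended stream decoded, the scene is remixed as
y_new = k·y + α1·ŝ1 + α2·ŝ2 under the constraints
20·log10((k+α1)/(k+α2)) = 9 dB, k+α1 = 1, α2 = 0, giving
k = 10^(−9/20) ≈ 0.355 and α1 ≈ 0.645 in closed form (`solveGains()`).
With ideal separation the attended stream keeps exactly its original
mixture power while the unattended stream and noise are attenuated by k.

The separation surrogate (`oracleSeparate()`) stands in for the trained
binaural network: ŝ = s + g·(y − s), with g chosen so the SNR improvement
(SNR(x, x̂) = 10·log10‖x‖²/‖x−x̂‖², capped at 120 dB) over the raw mixture
hits the requested target exactly; estimated trajectories are the truth on
12.5 Hz (80 ms) localizer frames plus Gaussian noise scaled to a target
mean absolute DOA error, snapped to the 1° classification grid (grid
resolution configurable; a 181-class grid is the default reading of the
localizer). Interaural features follow the printed definitions: cosIPD and
sinIPD of the STFT phase difference (32 ms window, 2 ms hop) and
ILD = 10·log10 of the magnitude ratio — deliberately 10·log10, not the
usual 20·log10 level-difference convention. Chance levels: 60° mean
absolute error for uniform azimuth pairs; 20% for five-sector
localization. The dilated-TCN receptive field of the (out-of-scope)
separation network is reproduced arithmetically:
1 + 5·Σ_b (3−1)·2^b frames over 7 blocks at 2 ms ≈ 2.54 s.

# Numerical choices and degenerate inputs

* Resampling is zero-phase FIR anti-aliased with linear interpolation onto the target grid; envelope outputs are clipped
  at zero against undershoot.
* The CCA ridge (1e−8, scaled by the mean covariance diagonal) only guards
  conditioning; canonical correlations are clipped to [0, 1].
* PCA uses eigen-decomposition of streamed covariances; if fewer than
  three canonical components survive, a warning is raised and voting uses
  what exists.
* Constant trajectories: stretch is skipped with a warning; correlation is
  defined as 0.
* Perfect behavioral rates are clipped to [1/(2N), 1−1/(2N)] before normal
  quantiles, so d′ stays finite.
* d′ is implemented verbatim as z(FA) − z(Hit) with right-tail z, which
  equals the textbook Φ⁻¹(hit) − Φ⁻¹(fa).
* Repeat scheduling is a bounded-retry sampler; an infeasible configuration
  (e.g. very short trials) errors naming the violated criterion rather
  than degrading.

# Problem sizes

The test suite and examples run the study at reduced scale, chosen so the
full pipeline exercises every contract in minutes on a laptop: 8-trial
experiments with 36 s trials (36 s keeps one 32 s decoding window per
trial), 12–16 synthetic channels, and a 100-trial scene audit at the full
40–50 s durations. The decoder's directional properties (window-size
monotonicity, trajectory contribution, behavior-correction benefit,
chance on shuffled labels) are all evaluated at these sizes.

# Known limitations

* The acoustic and neural generators are linear and stationary by design;
  none of the accuracy numbers here predict patient-level performance.
* The spatializer renders ITD/ILD but no spectral (pinna) cues or
  reverberation; externalization is not modeled.
* Speech is synthetic; there is no lexical content, so no forced alignment
  and no intelligibility testing (PESQ/ESTOI are out of scope — SNR-based
  metrics are reported instead).
* The separation surrogate is calibrated, not learned; it cannot exhibit
  channel-permutation errors, which is exactly why output-swap dynamics are
  *simulated* for transition-time analysis.
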