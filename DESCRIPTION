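Package: cocktailAAD
Title: Auditory Attention Decoding for Moving Multi-Talker Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale toolkit for brain-controlled augmented hearing
    research with spatially moving conversations. Simulates two-conversation
    acoustic scenes (first-order Markov-chain azimuth trajectories, turn-taking
    schedules, inserted repeated words for a 1-back attention probe, a
    spherical-head binaural renderer and diotic background noise), preprocesses
    multichannel intracranial recordings into 100 Hz high-gamma envelopes,
    generates synthetic neural data with the linear stimulus-tracking structure
    the decoder assumes, fits trajectory-augmented canonical correlation
    analysis (CCA) attention decoders with top-3 component voting, behavior
    correction from button-press responses and leave-one-trial-out evaluation,
    computes channel preference index (CPI) dynamics and transition times,
    solves the attended-stream enhancement gains, and evaluates binaural
    mixtures with signal-to-noise ratio, direction-of-arrival error and
    interaural phase/level difference features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils-dsp.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'trajectory.R'
    'scene-speech.R'
    'scene-spatial.R'
    'neural-preproc.R'
    'synthetic-neural.R'
    'stim-features.R'
    'cca.R'
    'decode.R'
    'behavior.R'
    'enhance.R'
    'metrics.R'
    'io.R'
    'experiment.R'
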