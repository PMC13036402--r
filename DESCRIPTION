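Package: pulsewave
Title: Smartphone Photoplethysmography Pulse-Waveform Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts fingertip-video frame stacks or raw single-channel
    photoplethysmography (PPG) traces into beat-segmented pulse waveforms and
    extracts a comprehensive time-, curvature- (acceleration PPG), and
    frequency-domain feature set with heart-rate and stature normalization.
    Includes signal-quality gating, a statistical pipeline (correlation-based
    feature selection, cluster-robust univariate regression with Bonferroni
    control, participant-grouped random-forest cross-validation, Bland-Altman
    agreement), and a ground-truth-labelled synthetic-data generator for
    pulsatile signals, camera frame stacks, and psychophysiological cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    randomForest,
    sandwich,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
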