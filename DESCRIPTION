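Package: audiobci
Title: Offline Decoding Pipeline for a Spatial Auditory P300 Brain-Computer
    Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and offline analysis of a multi-class auditory
    oddball brain-computer interface based on spatially distributed sound
    cues. Provides a synthetic EEG generator (constrained pseudo-random
    stimulus sequences, attention-dependent event-related potential
    templates, coloured background noise, line noise and ocular blink
    artifacts), preprocessing (causal or zero-phase Chebyshev II low-pass
    filtering, decimation to 100 Hz, epoching with baseline correction,
    threshold-based ocular artifact rejection), a signed ROC separability
    index with data-driven channel selection, shrinkage-regularized Fisher
    Discriminant classification under chronological cross-validation, and
    multi-class selection-accuracy and information-transfer-rate (Wolpaw)
    evaluation, including key-press response scoring for behavioural
    control conditions. Continuous signals can be exchanged as EDF+ files
    with tab-separated event-marker tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
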