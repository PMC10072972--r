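Package: gaitpli
Title: Time-Varying Phase-Lag-Index Connectivity of Gait-Aligned EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sliding-window phase-lag-index (PLI) analysis of multichannel
    EEG aligned to gait events. Provides a synthetic generator of
    phase-lag-coupled narrow-band oscillator recordings with gait schedules,
    standard EEG preprocessing (notch, band-pass, common-average reference,
    downsampling, event-locked epoching), windowed PLI connectivity tensors
    collapsed to gait phases, weighted brain-graph metrics in Brain
    Connectivity Toolbox conventions, one-way ANOVA across locomotion
    conditions, and connectivity-feature classification of locomotion state
    with SVM, naive Bayes and k-nearest-neighbour under stratified
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    e1071,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'simulate.R'
    'preprocess.R'
    'connectivity.R'
    'network.R'
    'features.R'
    'classify.R'
    'stats.R'
    'io.R'
    'pipeline.R'
    'utils.R'
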