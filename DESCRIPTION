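Package: crossmodal
Title: Quantification of Experience-Dependent Cross-Modal Suppression in
    Two-Photon Calcium Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify auditory-cue-driven suppression of visual
    responses in primary visual cortex from two-photon calcium imaging of
    audio-visual conditioning experiments. Provides median-normalized
    delta-F-over-F trace extraction, trial alignment, windowed
    baseline-subtracted response quantification, a response difference
    index, bin-by-bin significance testing with a consecutive-bin rule,
    responsive-cell classification, normalized optogenetic suppression,
    functional-influence (opto-tag) grouping, normality-gated test
    dispatch, anticipatory-lick and running-speed analysis with iterative
    speed-matched trial resampling, and visual-space receptive-field
    mapping. A synthetic-data generator simulates complete conditioning
    sessions (trial schedules, GCaMP-kernel calcium traces, licking,
    running, optogenetic sessions and rendered movies) with known ground
    truth so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    nortest,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'align.R'
    'behavior.R'
    'crossmodal-package.R'
    'dff.R'
    'groundtruth.R'
    'kernel.R'
    'pipeline.R'
    'receptive-field.R'
    'render.R'
    'schedule.R'
    'simulate-behavior.R'
    'simulate-neural.R'
    'stats.R'
    'studies.R'
    'utils.R'
    'windows.R'
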