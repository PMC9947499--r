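Package: eegavalanche
Title: Neuronal Avalanche and Event-Related Potential Analysis for
    Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cortical dynamics in multichannel EEG
    cohorts: simulation of resting-state recordings whose suprathreshold
    events form branching-process cascades, event-related potential (ERP)
    trial synthesis for three cognitive paradigms (face recognition, digit
    span, task switching), standard ERP and resting-state preprocessing
    pipelines (zero-phase Butterworth filtering, line-noise removal, scalp
    channel selection, decimation, common-average re-referencing, epoching
    and baseline correction), neuronal-avalanche feature extraction
    (thresholded event detection, time binning, cascade segmentation,
    discrete power-law exponent fitting by maximum likelihood, branching
    parameter estimation), grand-average cross-correlation ranking of
    electrodes, and linear discriminant classification of cohorts with
    stratified cross-validation and confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
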