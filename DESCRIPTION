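Package: socroc
Title: Social-Bout Modulation and Cross-Region Correlation Analysis for
    Joint Electrophysiology and Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for simultaneously recorded cerebellar spike
    trains and cortical calcium traces during social behavior. Detects
    social/object interaction bouts from position tracking, converts spike
    trains to frame-aligned smoothed z-scored rate series, classifies each
    unit or neuron as positively, negatively, or not modulated by
    interaction using ROC AUC against a circular-shuffle permutation null,
    builds peri-event time histograms and movement-confound checks, and
    measures cross-region Pearson correlations with circular-shift
    surrogate significance in full-session and non-social epochs. Includes
    a seeded synthetic-session generator (behavior, inhomogeneous Poisson
    spikes, calcium transients with planted cross-region coupling) so every
    stage is testable with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    patchwork,
    readr,
    jsonlite,
    yaml,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
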