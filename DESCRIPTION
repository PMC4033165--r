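Package: rtpercept
Title: Decoding the Content of Bistable Perception from BOLD Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and decoding of volume-by-volume conscious percepts
    (line versus integrated object) from functional MRI time series.
    Generates synthetic bistable-perception sessions with gamma-distributed
    percept dwell times, hemodynamic convolution, drift and autocorrelated
    noise; preprocesses runs (band-pass filtering, vessel-voxel exclusion,
    hemodynamic label shifting, spatial smoothing); selects voxels by
    GLM-contrast F tests; trains linear maximum-margin classifiers with
    leave-one-run-out cross-validation and in-fold low-pass optimization;
    simulates the causal real-time decoding loop with per-run retraining;
    quantifies reliability with block-preserving label permutation nulls for
    accuracy and per-voxel weights; and transfers accuracy-weighted group
    weight maps across subjects with leave-one-subject-out validation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
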