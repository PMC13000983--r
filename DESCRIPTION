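Package: wmswitch
Title: Priority-Switch Analysis for Two-Item Working Memory EEG Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for retro-cue working-memory experiments in
    which participants switch priority between two memorized orientations.
    Provides a synthetic-data generator that emulates the task structure,
    behavioral responses and multichannel EEG epochs with planted
    orientation tuning and condition-dependent oscillatory power;
    psychometric model fitting with lapse and swap parameters and
    switch-cost / item-distance analyses; spherical-spline surface
    Laplacian, Hanning-taper time-frequency decomposition and band-power
    extraction; cross-validated Mahalanobis-distance decoding of memorized
    orientations with shrinkage covariance; and group-level statistics
    including z-scored trial regressions, cluster-based sign-flip
    permutation tests, binned power-decoding analyses and repeated-measures
    ANOVA. All stages compose into a reproducible end-to-end study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
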