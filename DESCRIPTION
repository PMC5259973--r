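Package: pswalk
Title: Kinetic Gait Analysis from Pressure-Sensitive Walkway Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying limb use in quadrupeds from pressure-sensitive
    walkway (PSW) recordings, motivated by feline unilateral forelimb pain models.
    Provides a synthetic-data generator for walking and jump-landing trials with
    known ground truth, footfall detection and kinetic extraction (peak vertical
    force and vertical impulse, normalized to body weight), trial quality control
    on velocity and acceleration, forelimb symmetry indices and landing timing
    metrics, and the study-level statistics of a two-period crossover design:
    pain-score AUC comparisons with exact Wilcoxon signed-rank tests, ordinal
    repeated-measures pain models with baseline-probability crossing times,
    linear mixed models for baseline-adjusted kinetic responses, and contingency
    analysis of landing stagger counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    nlme,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
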