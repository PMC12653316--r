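Package: qeegratios
Title: Resting-State qEEG Lobar Power-Ratio Pipeline with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative EEG analysis pipeline for resting-state recordings:
    epoch extraction, average re-referencing, zero-phase bandpass filtering,
    deterministic artifact rejection, Welch power spectral density, relative
    band power, and lobar theta-alpha (TAR) and theta-beta (TBR) ratio
    indices, followed by a covariate-adjusted statistical layer relating the
    log-transformed ratios to a plasma oligomeric amyloid-beta biomarker
    (group tests with Cohen's d, Pearson correlations, unadjusted and
    adjusted linear models, education-stratified models, Bonferroni
    correction).  Includes a synthetic-cohort generator that produces
    multichannel 10-20 EEG with known spectral structure and a planted,
    configurable linear coupling between the biomarker and lobar log-TBR, so
    the whole pipeline is testable end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
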