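Package: ca125jm
Title: Joint Modelling of Longitudinal CA-125 Kinetics and Resectability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian joint modelling of serum CA-125 kinetics during
    neoadjuvant chemotherapy and the time to a resectability decision in
    advanced ovarian cancer. A linear mixed-effects sub-model describes
    log-square-root CA-125 trajectories adjusted for chemotherapy cycles and
    paracentesis; a proportional-hazards sub-model screens baseline
    covariates; the joint model links the two through a current-value
    association fitted by Metropolis-within-Gibbs. Includes subject-level
    dynamic prediction of the probability of a complete interval
    cytoreductive surgery decision, stratified cross-validated
    time-dependent AUC and Brier-type prediction error, fixed cut-off
    comparators, and a calibrated synthetic-cohort generator for
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    lme4,
    withr
Config/testthat/edition: 3
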