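Package: heterostat
Title: Torpor Metrics and Bayesian Maturation-Timing Models for Captive
    Heterotherm Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for temperature-manipulation experiments on
    heterothermic mammals. Computes individual torpor-onset thresholds from
    body mass and ambient temperature, detects torpor bouts in 10-minute
    skin-temperature logger series, and summarises daily thermoregulation
    effort (the skin-to-ambient temperature difference). Estimates the
    timing of ordinal sexual-maturation class transitions with a Bayesian
    hierarchical ordered-probit model on the day axis: per-transition
    baseline days, treatment delays, covariate effects in days, per-animal
    random intercepts, Gaussian imputation of missing covariates,
    multi-chain Markov chain Monte Carlo and Gelman-Rubin diagnostics. A
    seeded synthetic-cohort generator produces complete studies (cohort,
    logger traces, mass trajectories, ordinal examinations) so the whole
    pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
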