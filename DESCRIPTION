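Package: pitsim
Title: Simulation and Analysis of Aversive Pavlovian-to-Instrumental
    Transfer Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the coin approach/withdraw
    Pavlovian-to-instrumental transfer (PIT) task used to quantify human
    threat conditioning by key presses alone. Provides a stochastic
    simulator of the coin game (drifted random walk plus Gaussian
    key-press displacements), responder policies and calibration of the
    task dynamics; a synthetic multi-subject cohort generator with
    configurable effect sizes and condition-level psychophysiological
    amplitudes; extraction of response rate, response accuracy and
    first-press latency from long-format event logs; repeated-measures
    ANOVA with Greenhouse-Geisser correction and generalized eta squared,
    paired t-tests with Cohen's d and Bonferroni correction; AIC-based
    log Bayes factor comparison of the predictive validity of
    threat-learning measures; and power analysis for the one-sided paired
    t-test via the noncentral t distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
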