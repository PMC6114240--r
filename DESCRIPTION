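Package: promice
Title: Simulation Framework for Multiple Imputation of Multi-Item
    Patient-Reported Outcomes in Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the level at which missing
    patient-reported outcome measures (PROMs) are multiply imputed --
    composite score, subscale, or individual item -- affects trial
    estimates. Generates realistic two-arm randomised-trial cohorts with
    itemised instrument responses, imposes missing-at-random data with
    configurable mixtures of unit- and item-nonresponse patterns, imputes
    by chained equations using predictive mean matching and
    proportional-odds models with explicit convergence-failure semantics,
    pools estimates by Rubin's rules, and summarises performance (root
    mean square error, mean absolute error, reported standard errors,
    convergence failure rates) across scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
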