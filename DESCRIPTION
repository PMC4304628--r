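Package: selenotrial
Title: Multilevel Simulation of Selenium Chemoprevention Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links a mechanistic model of selenium metabolism and DNA damage
    to a multistage birth-death-mutation model of cancer onset, simulates
    ensembles of randomized two-arm prevention trials over virtual
    populations analyzed by Cox proportional-hazards regression, and
    performs value-of-information analysis with gradient boosted decision
    trees to identify which kinetic parameters dominate uncertainty in
    trial outcome. Includes constrained ensemble sampling under an
    incidence-calibrated baseline mutation rate, an exact Gillespie
    validator for the hazard solver, SBML subset import/export, and
    synthetic registry-style incidence generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    survival,
    xgboost,
    xml2,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
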