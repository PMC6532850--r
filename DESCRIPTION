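Package: faoflux
Title: Kinetic Modelling of Mitochondrial Fatty-Acid Beta-Oxidation Flux
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a linear cascade of irreversible first-order reactions to
    acylcarnitine time-course data to quantify mitochondrial fatty-acid
    beta-oxidation (FAO) flux. Concentrations are modelled with mass-action
    kinetics and optional zero-order influx terms, compared to data on log10
    scale under a log-normal error model, and estimated by multi-start
    maximum likelihood with profile-likelihood confidence intervals.
    Includes likelihood-ratio selection of influx reactions, rate-ratio
    (alpha) inference between knockdown and control conditions, the
    accompanying descriptive statistics (fold changes, acyl ratios,
    delta-delta-Ct with a reference-gene index, nonparametric group
    comparisons), and a synthetic time-course generator emulating
    doxycycline-inducible ACADS knockdown experiments in Huh7 cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    lhs,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
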