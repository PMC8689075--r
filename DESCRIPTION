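Package: tacropk
Title: Population Pharmacokinetics of Continuous-Infusion Tacrolimus in
    Pediatric Hematopoietic Cell Transplantation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical (nonlinear mixed-effects) modelling of tacrolimus
    given by continuous intravenous infusion to pediatric and young-adult
    hematopoietic cell transplant patients. Implements a two-compartment
    infusion model with allometric weight scaling and a CYP3A4/5-inhibitor
    covariate on clearance, log-normal inter-individual and inter-occasion
    variability, and proportional residual error. Provides closed-form
    kinetics, synthetic trial simulation emulating a daily trough-monitoring
    design, Laplace/FOCE-I marginal-likelihood estimation with empirical
    Bayes (MAP) individual estimates, stepwise covariate search, goodness of
    fit and visual predictive check diagnostics, and model-based (Bayesian
    forecasting) dose individualization to a trough target window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
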