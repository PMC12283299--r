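Package: remipopk
Title: Population Pharmacokinetics of Remimazolam Under Continuous Infusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-compartment population-pharmacokinetic analysis of
    remimazolam given by continuous intravenous infusion in critically ill
    patients. Provides the closed-form disposition model under arbitrary
    piecewise-constant infusion input, a synthetic-cohort generator that
    emulates the study design (sparse elimination-phase sampling, log-normal
    between-subject variability, proportional residual error), a first-order
    conditional estimation with interaction (FOCE-I) engine for nonlinear
    mixed-effects fitting with stepwise covariate screening by objective
    function value, internal-validation diagnostics (CWRES, nonparametric
    bootstrap, prediction-corrected visual predictive checks, normalized
    prediction distribution errors), and Monte Carlo dose simulation with
    context-sensitive decrement times.
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
    withr
Config/testthat/edition: 3
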