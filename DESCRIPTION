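Package: ipdinteract
Title: Treatment-Covariate Interactions in One-Stage IPD Meta-Analysis of
    Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-stage individual participant data (IPD) meta-analysis of
    time-to-event outcomes for estimating treatment-covariate interactions.
    Fits stratified Cox proportional-hazards models that either amalgamate or
    separate within-trial and across-trial interaction information, with fixed
    or trial-level random treatment effects (the latter by integrating the
    random effect out of the stratified partial likelihood with adaptive
    Gauss-Hermite quadrature).  Within-trial centring of patient covariates
    disentangles the within-trial interaction from the across-trial
    (ecologically biased) association, and the difference of the two estimates
    the magnitude of ecological bias.  Includes a survival-data simulator for
    multi-trial IPD with optional trial-level confounding, a Monte-Carlo study
    runner reporting bias, mean squared error and coverage of the interaction
    estimators, and a two-stage (per-trial then pooled) comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    survival,
    metafor,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
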