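Package: cardiosens
Title: Population-Based Regression and Bayesian Constraint of Cardiac Myocyte Model Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constrains free parameters (maximal ionic conductances and ion-transport
    rates) in ventricular myocyte electrophysiology models by population-of-models
    sensitivity analysis. Generates populations of randomized model variants of the
    Luo-Rudy 1991, ten Tusscher 2004, and a Bernus-type reduced human ventricular
    model, runs standard electrophysiological protocols (pacing, stimulation-threshold
    search, APD restitution, alternans scans, altered extracellular potassium,
    quiescence), extracts physiological outputs, fits forward and reverse multivariable
    regressions between log-scaled parameters and outputs, inverts the regression
    matrix on a greedily selected linearly independent output subset to predict
    parameters from outputs, reconstructs condition-induced parameter changes, and
    constrains parameters by sequential Bayesian conditioning on output windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
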