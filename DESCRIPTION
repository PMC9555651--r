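Package: stressdyn
Title: Fractional-Order Dynamics of a Socially Buffered Stress-Response Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a three-variable model of perceived
    psychological stress, stress-related ill-health and social support in
    which social support buffers the stress response and the dynamics carry
    memory through Caputo fractional derivatives. Provides an
    Adams-Bashforth-Moulton predictor-corrector integrator for Caputo
    initial value problems with an optional short-memory horizon,
    equilibrium location with fractional (Matignon) stability
    classification, Benettin-Wolf estimation of the Lyapunov spectrum with
    Kaplan-Yorke dimensions, spectral-entropy and C0-complexity summaries
    of simulated series, and bifurcation and regime-map scans over model
    parameters, forcing parameters and initial conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
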