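Package: racipe
Title: Random Circuit Perturbation Analysis of Gene Regulatory Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterizes the robust dynamical features of a gene regulatory
    circuit from its topology alone.  An ensemble of ordinary-differential-
    equation models with shifted-Hill regulation is generated by independently
    randomizing every kinetic parameter (production, degradation, Hill
    coefficient, fold change, and numerically estimated "half-functional"
    thresholds), each model's stable steady states are enumerated by
    multi-start integration, and the ensemble is analyzed statistically:
    hierarchical clustering and principal components of the pooled expression
    states, state-count distributions, in-silico gene knockout and
    over/under-expression, and Bhattacharyya-distance convergence diagnostics
    for the ensemble size and the number of initial conditions.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
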