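Package: phasetree
Title: Coxian Phase-Type Models for Macroevolutionary Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying speciation and extinction with Coxian
    phase-type (PH) waiting-time distributions. Provides constructors,
    densities, moments, hazard rates and samplers for Coxian PH
    distributions; a forward-in-time species-tree simulator with
    arbitrary waiting-time distributions and symmetric or asymmetric
    speciation; tree-balance statistics (per-tree and pooled treeset
    beta with profile confidence intervals, and the gamma statistic);
    matrix-exponential likelihoods of reconstructed trees under PH,
    exponential, Weibull and constant-rate birth-death models; and
    maximum-likelihood fitting with AIC model comparison and
    Kolmogorov-Smirnov goodness-of-fit via simulation. Includes a
    command-line interface for reproducible simulation and fitting runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
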