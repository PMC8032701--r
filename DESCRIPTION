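Package: actihsmm
Title: Zero-Inflated Poisson Hidden Semi-Markov Models for High-Frequency
    Activity Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits explicit-duration (semi-Markov) latent-state models to
    minute-epoch accelerometer activity counts with zero-inflated Poisson
    emissions, covariate-dependent state dwell times (discretized accelerated
    failure time), and multinomial-logit transitions. Provides exact
    forward-recursion likelihood evaluation, subject-level maximum-likelihood
    estimation with BIC selection of the number of latent states, Viterbi
    decoding with occupancy summaries and quantile-based fit checks, two-stage
    population-level treatment-effect inference with heteroskedasticity-robust
    (sandwich) standard errors and Wald tests, a crossover-study simulator for
    validation, and a command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
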