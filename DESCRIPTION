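Package: bayeschoice
Title: Bayesian Sequential Sampling Models of Attention- and
    Confidence-Weighted Value-Based Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, fitting and analysis tools for a Bayesian
    sequential-sampling account of binary value-based choice in which
    attention (presentation time) controls the quantity of value samples
    and rating confidence controls their precision. Implements conjugate
    Gaussian belief updating over item values, an approximate
    value-of-computation stopping rule in the Directed Cognition family,
    alternative model variants (zero prior, flat prior, equal-weight
    updating, biased confidence), grid-search parameter fitting on
    summary statistics, a synthetic-experiment generator matching a
    standard two-alternative forced-choice design with exogenous
    presentation schedules, and regression-based tests of the model's
    reference-dependent choice signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
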