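Package: kanocca
Title: Kano Quality-Attribute Classification with Cultural Consensus Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of two-question (functional/dysfunctional) Kano
    satisfaction questionnaires. Classifies product or intervention
    attributes into the six Kano categories (must-be, one-dimensional,
    attractive, indifferent, reverse, questionable) under three rules:
    the original modal rule, Blauth's revised pooled-relevancy rule, and
    a consensus-based rule driven by the latent item truth of a Bayesian
    General Condorcet Model. Computes Timko better/worse importance
    coefficients and quadrant placements, fits the General Condorcet
    Model (respondent competency and guessing bias, item difficulty and
    latent truth) by Markov chain Monte Carlo, detects the number of
    consensus groups from the eigenvalue spectrum of the
    respondent-respondent correlation matrix, and ships synthetic-data
    generators so every stage can be exercised end to end without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
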