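Package: stablefc
Title: Stable Estimation of Time-Varying Functional Connectivity States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variational-Bayes inference of hidden Markov models with
    zero-mean Gaussian observations and full state covariances, for
    estimating time-varying functional connectivity (FC) states from
    multichannel neural time series. Because the inference starts from a
    random point, different runs can land on different solutions; the
    package implements two ensemble procedures that stabilize the
    estimates: best-ranked selection, which keeps the run with the lowest
    variational free energy among R restarts, and hierarchical-clustered
    aggregation, which pools the R x K state time series across runs by
    Ward clustering on one-minus-Pearson distance and aggregates each
    cluster into a single state. Includes session-aware dynamics (the
    first sample after a recording discontinuity is modeled with the
    initial distribution), Hungarian state alignment and a normalized
    between-run similarity score, repetition-based stability protocols,
    per-state dynamic metrics, and a seeded Markov-switching Gaussian
    simulator with a tunable state-separation dial.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    clue,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
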