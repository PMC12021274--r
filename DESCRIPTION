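Package: sebtim
Title: Resource-Limited Observer Models of Rapid Numerosity Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements two competing bounded-resource observer models of rapid
    numerosity estimation: a sequential-encoding/Bayesian-decoding observer
    (SEB), in which viewing time limits the precision of a noisy logarithmic
    sensory code that is decoded by a minimum mean-squared-error Bayesian
    read-out, and a thermodynamically inspired observer (TIM), in which
    responses are shifted away from a default distribution under a
    Kullback-Leibler information budget. Provides trial-level likelihoods,
    per-participant maximum-likelihood fitting by differential evolution with
    AIC model comparison, bootstrap and paired-test cohort summaries,
    parameter- and model-recovery studies, and a synthetic behavioral-data
    generator reproducing the design of rapid estimation experiments
    (numerosities 1-15 crossed with presentation durations or contrast levels).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
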