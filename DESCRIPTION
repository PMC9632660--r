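Package: epitarget
Title: Epileptic Network Inference and Neuromodulation Target Localization
    from Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Infers directed epileptic brain networks from multichannel
    intracranial EEG using the directed transfer function with
    phase-randomization surrogate analysis, alongside eight alternative
    connectivity estimators (Pearson correlation, partial directed coherence,
    isolated effective coherence, weighted phase lag index,
    Kullback-Leibler spectrogram divergence, each with or without surrogate
    thresholding).  The inferred network parameterizes a multi-unit bistable
    stochastic oscillator model in which every channel is a node with an
    excitability parameter; channels are ranked as neuromodulation targets by
    the change in network escape time when a single node's excitability is
    raised.  Includes excitability grid search, virtual resection,
    rank-sum validation of the localized target, synthetic multivariate
    autoregressive benchmarks, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
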