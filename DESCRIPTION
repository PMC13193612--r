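Package: pursuitlab
Title: Simulation and Analysis of Hidden-Intention Inference in a
    Prey-Pursuit Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A multi-agent prey-pursuit game simulator with a hidden
    opponent-intention parameter, a synthetic-participant generator with
    known ground-truth decision parameters, and the analysis stack used to
    study social inference in that task: psychometric and signal-detection
    summaries of boost/hinder choices, Shannon entropy of choice, an
    autoregressive logistic model of intention inference with a hysteresis
    term, energy-landscape reconstruction of inference dynamics (binned
    drift, potential, fixed points, basin geometry), gaze-allocation and
    control-stability metrics with cluster-based permutation testing, and a
    three-step LSTM adaptation experiment with an asymmetric
    betrayal-sensitivity loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
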