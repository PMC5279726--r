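Package: pitchadapt
Title: Bayesian Causal-Inference Model of Vocal Adaptation to
    Pitch-Shifted Auditory Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and fits a Bayesian causal-inference model of vocal
    pitch control under pitch-shifted auditory feedback, as studied in
    songbirds and humans.  A vocalizer combines an internal motor
    prediction with noisy auditory feedback, weighs the combined estimate
    by the posterior probability that the feedback was self-caused, and
    slowly retunes its motor plan until the perceived pitch error
    vanishes.  The package provides the generative model and inference
    equations, stochastic and deterministic equilibrium solvers for the
    corrective pitch bias, compensation curves against shift magnitude,
    motor variability and sensory noise, a random-search fitting routine
    for compensation datasets, synthetic-data generators with known
    ground truth, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
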