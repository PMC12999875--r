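Package: hueforage
Title: Generative Modelling of Continuous-Feature Visual Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian inference for visual
    foraging tasks in which targets vary along a continuous feature
    dimension (hue on a circular, perceptually linearised colour space).
    Provides a synthetic stimulus and session generator (truncated-Gaussian
    target distributions flanked by uniform distractor bands on a 48-hue
    circle), a sequential sampling-without-replacement choice model with
    colour-tuning, switch, proximity and direction biases, a forward
    simulator, multilevel Bayesian estimation via a built-in No-U-Turn
    sampler with non-centered random effects and an LKJ correlation prior,
    Pareto-smoothed importance-sampling leave-one-out model comparison,
    and descriptive summaries of foraging behaviour.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
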