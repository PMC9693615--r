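Package: cobe
Title: Correlated Beta Processes for Adaptive Vaccine Dose Optimisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for adaptive vaccine dose-finding
    trials built on the non-parametric Continuous Correlated Beta Process
    (CCBP). Per-dose beta posteriors over binary efficacy and toxicity are
    updated with fractional pseudo-counts weighted by a squared-exponential
    dose-similarity kernel, trial doses are chosen by Thompson sampling, and
    the final dose maximises the utility of the posterior medians ('CoBe'
    dose optimisation). Includes three comparator strategies (a latent
    quadratic/linear parametric design with softmax allocation, an adaptive
    naive beta-Bernoulli design, and uniform allocation), efficacy-toxicity
    utility contours, expert-elicited beta priors, a catalogue of synthetic
    dose-response scenarios for single, prime/boost and
    prime/boost/second-boost administration, and a replicated simulation-study
    engine with per-cohort evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
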