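Package: respmeta
Title: Breathing Interoception and Metacognition from the Filter Detection Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying breathing-related interoception from the
    Filter Detection Task (FDT): perceptual threshold, type-1 signal detection
    parameters (d-prime and decision bias), metacognitive bias (mean
    confidence), and metacognitive insight (meta-d-prime based logMratio)
    estimated by single-subject maximum likelihood and by a hierarchical
    Bayesian model sampled with JAGS. Includes an embedded hierarchical
    regression of subject logMratio on psychological covariates with
    gender-interaction and gender-specific-slope designs and 95 percent
    highest-density-interval inference, ordinary least-squares analyses of
    the remaining measures, a risk-controlled adaptive staircase simulator
    for the task difficulty algorithm, and a synthetic-cohort generator with
    planted effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda
Config/testthat/edition: 3
RoxygenNote: 7.3.3
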