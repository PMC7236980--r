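Package: imtfit
Title: Effort-Discounting Models for the Internal-External Motivation Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits psychometric effort-by-reward discount curves (linear,
    sigmoid and Weibull) to data from the Internal-External Motivation Task
    (IMT), an effort-discounting paradigm that separates self-generated
    (internal) from externally-generated (external) motivation. Provides
    maximum-a-posteriori model inversion with Laplace-approximated model
    evidence, an iterated empirical-Bayes group prior, random-effects
    Bayesian model selection with protected exceedance probability and
    Bayesian omnibus risk, between-conditions model-stability testing,
    simulation-recovery reliability analysis, group-level condition
    contrasts and questionnaire correlations, and a synthetic-cohort
    generator emulating both the physical- and cognitive-effort task
    variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
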