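Package: boubataste
Title: Bayesian Within-Subjects Analysis of Shape-Taste Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Bayesian analysis of a four-condition within-subjects sensory
    experiment in which participants rate the sweetness, sourness and
    bitterness of rounded ("Bouba") and angular ("Kiki") chocolate shapes on
    a 0-100 visual analogue scale.  Implements the multivariate-normal model
    with Uniform priors on condition means and standard deviations and an
    LKJ prior on the correlation matrix, an adaptive random-walk Metropolis
    sampler on an unconstrained parameterization, split Gelman-Rubin
    convergence diagnostics, EAP/posterior-SD/HDI summaries, draw-wise
    directional hypothesis probabilities and compound group-comparison
    probabilities, plus a synthetic-data generator with Latin-square
    presentation orders so the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
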