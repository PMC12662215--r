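Package: peacetrace
Title: Climate, Demography, and the Probability of Peaceful Interactions
    in Skeletal Trauma Records
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end inference pipeline linking Holocene climate,
    relative population density, and socio-political complexity to the
    probability that an adult skeletal individual shows no craniofacial
    trauma (the probability of peaceful interactions, PPI). Covers
    radiocarbon calibration and composite kernel density (CKDE) population
    proxies with optional taphonomic correction, Monte-Carlo propagation
    of each individual's temporal uncertainty into climatic, oceanic and
    demographic exposure draws, iterated probability-forest ensembles with
    collinearity screening, per-site subsampling and stratified
    evaluation, permutation variable importance, partial-dependence
    aggregation with PPI ranges, and a synthetic-world generator with a
    known logistic trauma model so every stage is testable against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
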