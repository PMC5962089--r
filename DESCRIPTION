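Package: favsec
Title: Favourability Modelling and Insecurity-Index Gap Analysis of
    Protected-Area Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models species distributions on a grid with stepwise logistic
    regression and the favourability transform, then quantifies how well a
    protected-area network covers favourable areas using the per-cell and
    overall Insecurity Index, Security, and Representativeness, with a
    permutation null model for the network. Includes predictor screening
    (within-set correlation pruning, a trend-surface spatial descriptor and
    false-discovery-rate filtering), model evaluation (Cohen's kappa,
    sensitivity, specificity, correct classification rate, AUC and the
    Hosmer-Lemeshow test), a synthetic-landscape generator producing
    correlated predictors, virtual species and park-like fractional coverage
    layers, and an end-to-end pipeline with CSV and ESRI ASCII grid output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
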