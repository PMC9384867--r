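Package: enmpair
Title: Climate-Suitability Modelling and Niche Overlap for Parasite-Host Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Presence-background maximum-entropy species distribution
    modelling for parasite-host species pairs under climate-change
    scenarios.  Provides an ESRI ASCII grid raster layer, occurrence
    cleaning and spatial rarefaction, Pearson-correlation variable
    filtering, a maximum-entropy engine with linear, quadratic, product,
    hinge and threshold features and per-feature L1 regularization, AICc
    tuning over regularization multipliers and feature classes, replicate
    AUC/TSS evaluation, habitat-suitability classification and area-trend
    typologies, Schoener's D niche overlap with one-way ANOVA and Tamhane
    T2 post-hoc letters, a synthetic climate and occurrence generator for
    self-contained testing, and an end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
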