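Package: responderRF
Title: Multi-Omics Random-Forest Classification of Dietary Weight-Loss Responders
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to classify weight-loss responders and non-responders in
    crossover dietary-intervention cohorts from baseline multi-omics feature
    blocks (diet arm, clinical variables, 16S and shotgun microbiome
    abundances, urine metabolites, SNP dosages and genetic risk scores, and
    postprandial time-series volatility features). Implements relative
    weight-change outcome labelling, postprandial curve rasterization and
    fluctuation features, abundance normalization, variance-inflation-factor
    SNP pruning, weighted genetic risk scores, a fixed-specification random
    forest evaluated under repeated stratified cross-validation, wrapper
    forward feature selection, label-permutation robustness tests, and
    confidence-gated model ensembles with clinical threshold sweeps. Ships a
    synthetic cohort generator with planted effects and block-wise
    missingness so the whole pipeline runs and validates without access to
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
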