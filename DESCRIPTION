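Package: ramanphen
Title: Label-Free Raman Phenotyping of Macrophages by Spectral Unmixing
    and PCA-LDA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for phenotyping single macrophages from
    hyperspectral Raman image scans. Provides spectral preprocessing
    (cell masking, cosmic-ray despiking, fluorescence-outlier screening,
    silent-region removal and SNIP baseline correction), N-FINDR endmember
    extraction with non-negative least-squares abundance estimation and
    grouping into biochemical component maps, lipid band-integral ratios
    (including the 1655/1444 cm-1 unsaturation ratio), and PCA-LDA
    discrimination of pro-inflammatory (M1) versus non-pro-inflammatory
    (M0/M2) phenotypes under leave-one-donor-out cross-validation. A
    synthetic hyperspectral scene generator with full ground truth supports
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    png,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
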