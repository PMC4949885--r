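Package: snpnoise
Title: Label-Noise Robustness of SNP-Based Binary Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation toolkit for assessing how random phenotyping errors
    (flipped binary labels) affect genomic predictions for a binary plant
    trait. Includes a seeded synthetic sugar-beet population generator with
    realistic marker-panel structure, genotype quality control (call-rate
    filter, k-nearest-sample imputation, minor-allele-frequency filter),
    controlled label flipping, five classification models (distance-weighted
    K-nearest neighbours, random forest, ridge-penalised logistic regression,
    and support vector machines with linear or radial basis function kernels)
    under a uniform fit/score contract, nested repeated stratified
    cross-validation with hyperparameter tuning, ROC/AUC evaluation, and a
    noise-ladder experiment runner with figure and table reporting.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    ranger,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    e1071,
    pROC
Config/testthat/edition: 3
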