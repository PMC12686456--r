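Package: semogen
Title: Multi-Objective Genetic Feature Selection with Regularized MLP
    Ensembles for Cardiovascular Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage prediction framework for tabular binary clinical
    cohorts such as the Cleveland heart-disease data. A binary-chromosome
    multi-objective genetic algorithm (non-dominated sorting with crowding
    distance) selects compact feature subsets under a four-part wrapper
    fitness: cross-validated accuracy, mean absolute pairwise correlation
    (redundancy), a clinician-assigned interpretability score, and the
    geometric mean of sensitivity and specificity. Representative Pareto
    subsets then train an ensemble of L2-regularized dropout multilayer
    perceptrons fused by uniform averaging, fitness-derived weighting, or
    AdaBoost. Includes cohort readers for CSV and the UCI "processed"
    dialect, preprocessing (imputation, min-max scaling, one-hot encoding,
    SMOTE), a synthetic cohort generator with planted signal for testing,
    imbalance-aware diagnostics (G-mean, MCC, Q-statistic, entropy
    diversity), and experiment harnesses for robustness, ablation and
    cross-validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
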