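Package: ProteoDx
Title: Multi-Task Joint Learning for Plasma-Proteomic Diagnosis of Dementia-Associated Conditions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating multi-task diagnostic
    classifiers on high-dimensional plasma proteomics. Provides a
    SummarizedExperiment-based cohort container with ternary (positive /
    negative / missing) labels for six dementia-associated conditions,
    synthetic cohort simulation with planted ground truth, site-aware
    cross-validation and leave-one-site-out splitting, a fitted
    preprocessing chain (outlier masking, average-level normalization,
    nearest-neighbour imputation, Gaussian rank normalization), two-stage
    feature selection (per-protein linear-model association plus
    boosted-tree consensus), a shared-trunk multi-task neural network
    trained with label-smoothed cross-entropy and a pairwise rank loss,
    permutation feature importance, Haufe covariance interpretation of
    embeddings, probability-map subtyping, few-shot transfer to new sites,
    and two-cutoff predictive-value calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    data.table,
    xgboost,
    glmnet,
    MASS,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, Classification, MachineLearning, Software
RoxygenNote: 7.3.3
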