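Package: pdcog
Title: Multimodal MRI Machine-Learning Detection of Early Cognitive
    Impairment in Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for classifying Parkinson's disease patients
    with beginning cognitive deficits (MoCA-defined) from multimodal MRI
    features. Builds inter-network functional-connectivity features
    (band-pass filtered parcellated time series, pairwise Pearson
    correlation, Fisher r-to-z), assembles modality scenarios combining
    gray-matter volumes, connectivity and clinical covariates, ranks
    features by bootstrapped greedy forward selection under a linear
    support vector machine, exhaustively searches small feature subsets
    over an SVM kernel/hyperparameter grid with repeated stratified
    cross-validation, and supplements the multivariate models with
    covariate-adjusted univariate ANCOVA under Benjamini-Hochberg FDR
    control. A synthetic cohort generator with configurable planted group
    effects makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    parallel,
    signal,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
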