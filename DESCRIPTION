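Package: fibrodep
Title: Differential Co-Expression Feature Selection and SVM Classification
    of Depression in Fibromyalgia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for differentiating major depression in fibromyalgia
    patients from pain-pathway gene expression. Per-group absolute Pearson
    correlation distributions are compared with a two-sample
    Kolmogorov-Smirnov test to locate a disease-specific co-expression
    cutoff; gene pairs are partitioned into disrupted, invoked and common
    links; hub genes are ranked by Rsum connectivity and selected as
    classifier features; samples are augmented with additive Gaussian noise
    at a controlled signal-to-noise ratio; and an RBF-kernel support vector
    machine is trained on PCA-reduced features with repeated stratified
    K-fold grid search under two cross-validation schemes. Includes a
    synthetic-data generator with planted group-specific correlation blocks
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
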