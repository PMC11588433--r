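Package: plaqsig
Title: Co-Expression Signatures and Gene-Immune Portrait Classifiers for
    Atherosclerotic Plaque Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for distinguishing early from advanced
    carotid atherosclerotic plaques from bulk gene expression. Provides a
    synthetic cohort generator with planted cell-type mixtures, diagnostic
    signatures and co-expression modules; a weighted co-expression core
    (soft-threshold scan, topological overlap, module detection, eigengenes,
    kME, hub-gene selection); univariate screening plus L1-penalised logistic
    signature selection; marker-based immune abundance scores, single-sample
    gene-set enrichment and bin-matched module scores; non-negative matrix
    factorisation subtyping; a repeated cross-validation multi-model
    benchmark with ROC/AUC and Youden threshold reporting; and a per-patient
    gene-immune ratio "portrait" classified by a small convolutional neural
    network implemented natively.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
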