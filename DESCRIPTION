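Package: tanprog
Title: Prognostic Co-Expression Module Analysis of Tumor-Adjacent Normal Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for prognostic analysis of
    matched tumor and tumor-adjacent normal (TAN) RNA-seq cohorts:
    median-of-ratios normalization and variance-stabilizing-style
    transformation, unsupervised co-expression module discovery (gene-space
    PCA followed by partitioning-around-medoids clustering), per-sample
    module scoring, one-tailed Fisher gene-set enrichment, an elastic-net
    logistic recurrence classifier with nested cross-validation and pooled
    out-of-fold ROC/DeLong evaluation, Kaplan-Meier/log-rank/Cox/c-index
    survival association of module scores, cell-type-resolved module scoring
    on deconvolved expression, and somatic-variant filtering for tumor
    mutational burden. A synthetic matched tumor-normal cohort generator
    with planted module structure and survival signal makes every stage
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    survival,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    glmnet,
    jsonlite,
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
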