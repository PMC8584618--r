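Package: olfrisk
Title: Olfactory Function and Diabetes-Risk Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-stage framework for deciding whether one block of
    clinical features (olfactory test scores) carries information about a
    grouping defined by another block (metabolomics and a diabetes risk
    score). Implements Pareto density estimation and univariate Gaussian
    mixture mode decomposition with Bayesian decision boundaries,
    PCA-Ward-k-means subgroup discovery with a cluster-number index
    majority vote, classical association statistics (chi-squared crosstabs
    with Pearson residuals, Bonferroni-controlled correlation matrices,
    mixed repeated-measures ANOVA), a permutation-controlled Monte-Carlo
    cross-validation classification harness over five classifier families,
    and resampled feature selection (shadow-feature testing, LASSO, LMG
    relative importance) aggregated by computed ABC analysis. A synthetic
    cohort generator emulates the statistical structure of an olfactory /
    metabolomics / diabetes-risk study so every stage is testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    ranger,
    xgboost,
    rpart,
    e1071,
    glmnet,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    mclust,
    cluster,
    car
Config/testthat/edition: 3
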