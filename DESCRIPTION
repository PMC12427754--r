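Package: tepmced
Title: Interpretable Multi-Cancer Detection from Tumor-Educated Platelet RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for interpretable multi-cancer
    early detection from tumor-educated platelet RNA expression profiles.
    Provides cohort curation with exclusion of symptomatic controls,
    three-stage feature selection (ANOVA screening with
    Benjamini-Hochberg control, a gene cap, and greedy correlation
    pruning), a covariate-balanced train/test partition obtained by
    constrained optimization over age, sex, cancer type and institution,
    a seven-family classifier zoo (shallow and deep neural networks,
    gradient boosting, support vector machine, random forest, logistic
    regression, decision tree) with leak-proof in-fold SMOTE resampling
    and scaling, Youden-J threshold calibration, Shapley-value
    attribution per model family with adaptive IQR outlier filtering,
    and an AUC-weighted cross-model consensus gene ranking with
    Spearman agreement diagnostics. A synthetic platelet-RNA cohort
    generator with planted informative genes provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    ranger,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
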