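---
title: "Methods: interpretable multi-cancer detection from platelet RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable multi-cancer detection from platelet RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Tumor-educated platelets (TEPs) carry RNA signatures that are altered
by the presence of a tumor, which makes platelet expression profiles a
candidate substrate for minimally invasive multi-cancer early
detection. `tepmced` implements a complete, testable version of such a
study: cohort curation, feature selection, covariate-balanced data
splitting, a zoo of binary cancer-vs-control classifiers, per-model
Shapley attribution, and a cross-model consensus gene ranking. This
vignette documents each modeling choice, the parameters that control
it, and the numerical methods behind the less standard steps.

## Synthetic cohorts as ground truth

Real platelet expression matrices are large, access-controlled, and
carry no ground truth about which genes *cause* the class difference.
The package therefore ships a synthetic cohort generator,
`generate_cohort()`, whose defaults mirror a realistic study:
2351 samples (1628 cancer, 723 control, of which 333 controls are
flagged as symptomatic and excluded before analysis), 2000 genes, 18
cancer types with a stage distribution, four contributing institutions,
and age/sex covariates.

Expression is drawn from a latent-factor model: genes are organized in
blocks of `block_size = 10` sharing a latent factor with loading
`sqrt(block_rho)` (`block_rho = 0.3`), which produces the modest
gene-gene correlation structure typical of co-expressed transcripts. A
configurable set of `n_informative = 20` genes receives a mean shift of
`effect_size = 1.5` standard deviations in cancer samples; flagged
symptomatic controls receive a half-strength perturbation on a random
10% of genes, making them mildly atypical rather than cancer-like —
this is what makes their exclusion consequential and testable.

What the generator deliberately does *not* model: library-size and
batch effects, count-level noise (values are Gaussian z-like scores,
not counts), cancer-type-specific signatures (the planted signal is
shared across types), and covariate-expression confounding. The
generator's job is to provide controlled ground truth for the
pipeline's behavior, not to simulate sequencing.

`generate_external_cohort()` draws a second cohort from the same model
— fresh samples, the same planted genes, an optional subset of the gene
panel, and a configurable number of samples copied verbatim from the
primary cohort to emulate inter-dataset sample overlap that must be
deduplicated before external validation
(`harmonize_external()`).

## Three-stage feature selection

`select_features()` reduces 2000 genes to a model-ready panel in three
stages, all computed on a label-stratified *discovery subset*
(`discovery_fraction = 0.33`) so that the bulk of the data never
informs gene screening:

1. **ANOVA screening.** A one-way ANOVA F-test per gene
   (cancer vs control), with Benjamini–Hochberg control at
   `fdr = 0.001`. Constant genes are assigned q = 1.
2. **Cap.** At most `cap = 300` genes are retained, preferring the
   smallest q (ties broken toward the larger F).
3. **Correlation pruning.** A greedy pass in ascending-q order drops
   any gene whose absolute Pearson correlation with an already-retained
   gene exceeds `r_threshold = 0.8`; zero-variance genes are treated as
   uncorrelated.

Per-fold z-scaling is fitted inside each training fold only
(`fit_scaler()` / `apply_scaler()`); a zero-variance gene maps to 0
rather than NaN.

## Covariate-balanced splitting

A plain random split of 2018 samples can leave the 20% test set
imbalanced in sex, age, institution or cancer type.
`optimize_split()` minimizes an explicit divergence
(`split_divergence()`): the sum over the categorical covariates (label,
sex, cancer type, institution) of squared test-vs-train
category-proportion gaps, plus the squared standardized difference of
age means.

The combinatorial assignment problem is relaxed to continuous
test-membership weights $w \in [0,1]^n$ with $\sum w_i = m$ (the test
size, `round(0.2 * n)`). The relaxation is solved by projected gradient
descent with analytic gradients and a backtracking step size; the
projection onto the capped simplex is computed by bisection on the
shift in $\mathrm{clamp}(w - \tau, 0, 1)$. The solution is rounded to
the $m$ largest weights and then polished by a randomized
swap hill-climb (`50 n` candidate test/train exchanges, each evaluated
incrementally in O(#levels) via per-category test-side counts). If the
optimizer somehow fails to beat its stratified random start, the start
is kept and a warning is raised. For calibration, the divergences of
`n_baseline` stratified random splits are recorded, so an optimized
split can always be judged against the random-split distribution.

## Classifier zoo

`model_config()` / `tune_and_fit()` train any of seven families under a
fixed pipeline order — **resample → scale → classify** — where every
stage is fitted inside each cross-validation training fold only:

* class imbalance is corrected with SMOTE (`smote()`, k = 5 minority
  neighbors, interpolation between a minority sample and one of its
  neighbors), implemented in the package so the synthetic rows can be
  tracked and asserted on in tests;
* the z-scaler is fitted on the resampled fold-training rows;
* the classifier is fitted on the scaled rows.

Families: shallow (`NN`) and deep (`DNN`) multilayer perceptrons
(implemented in R: Glorot-uniform initialization, ReLU with inverted
dropout, sigmoid output, Adam, binary cross-entropy, early stopping
with best-weight restoration), gradient boosting (`xgboost`), RBF SVM
(`e1071`), probability random forest (`ranger`), elastic-net logistic
regression (`glmnet`) and a decision tree (`rpart`).

Hyperparameters are chosen by randomized search (8 draws per family, 5
for the deep network) over small literature-typical grids, scored by
mean rank-based AUC over stratified 5-fold cross-validation. The
decision threshold is calibrated by maximizing Youden's J on the pooled
out-of-fold predictions, scanning midpoints of consecutive unique
scores and taking the smallest maximizer. Evaluation
(`classification_metrics()`) reports sensitivity, specificity,
accuracy, balanced accuracy, precision, F1, rank-based AUC and average
precision, with undefined ratios reported as `NA` and flagged rather
than silently zeroed.

## Shapley attribution per family

`compute_attributions()` explains each trained pipeline with the
backend best suited to the family:

* **LR** — closed form for a linear model on the log-odds scale:
  $\phi_j = \beta_j (z_j - \bar z^{bg}_j)$.
* **XGB** — the booster's exact tree-path attribution
  (`predcontrib`), also on the log-odds scale.
* **NN / DNN** — expected gradients: integrated gradients of the
  pre-sigmoid output along straight paths from up to 25 background
  samples, midpoint rule with 20 steps by default. Completeness
  (attributions summing to the prediction minus the base value) holds
  up to the integration error, which the test suite bounds.
* **SVM / RF / DT** — kernel Shapley regression on the probability
  output. When the $2^p - 2$ proper coalitions fit the budget
  (`nsim = 512`), the exact weighted least-squares problem is solved
  with the efficiency constraint eliminated analytically, recovering
  exact Shapley values of the interventional game; otherwise coalitions
  are sampled from the Shapley-kernel size distribution. Because each
  coalition costs one model evaluation per background row, the
  background for these families is compressed to 50 k-means
  representatives (`select_background()`), and the number of explained
  samples is capped (`max_eval = 50`) with a warning.

All backends operate in the model's scaled feature space and record the
background specification and output scale alongside the values.

## Adaptive outlier filtering

Raw attribution matrices contain occasional extreme values that can
dominate a global mean. `filter_outliers()` zeroes, per gene, the
values outside $[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]$,
choosing $k$ adaptively: the grid $3.0, 2.75, \ldots, 0.5$ is scanned
from the least aggressive end and the first $k$ whose zeroed fraction
falls in `ratio_band = [0.05, 0.10]` wins. If no multiplier reaches the
band (e.g. a tight body with a few detached extremes), a fallback
zeroes exactly the points outside the empirical 1st/99th percentiles;
zero-IQR genes are left untouched. The filtered matrix drives global
importance (`global_importance()`, mean absolute attribution);
unfiltered values are kept for local explanations
(`local_explanation()`) and dependence data (`dependence_data()`, with
a slope-contrast heuristic for picking an interaction partner).

## Consensus and agreement

`weighted_consensus()` min-max scales each model's importance vector
across genes, weights it by the model's test AUC, and sums over models;
the decision tree is excluded by default because single-tree
attributions are unstable, but it remains available to
`agreement_matrix()`, which reports pairwise Spearman correlations over
genes with nonzero importance in both models (pairs sharing fewer than
3 genes are `NA`). `topk_overlap()` compares the top-k genes of two
rankings, e.g. primary vs external cohort.

## Problem sizes and reproducibility

The defaults target the full synthetic design (2018 analyzed samples,
2000 genes, 300-gene cap). The driver `run_pipeline()` chains all
stages under one master seed; every stochastic component (generator,
discovery subset, split initialization, fold assignment, SMOTE,
hyperparameter draws, coalition sampling) is seeded deterministically
from it, so results are bit-reproducible. A typical full run with the
fast, exactly-attributable families (`LR`, `XGB`) completes in minutes
on one CPU:

```{r}
library(tepmced)
cohort <- generate_cohort(cohort_config(seed = 1))
result <- run_pipeline(cohort, families = c("LR", "XGB"), seed = 1,
                       n_baseline = 1000)
head(result$consensus$scores, 15)
```

## Limitations

* The generator's Gaussian, type-agnostic signal makes recovery easier
  than in real platelet data; recovery rates here are upper bounds.
* Kernel-backend attributions are exact only when coalition enumeration
  fits the budget (p ≤ 9 at the default `nsim`); beyond that they are
  sampling-based estimates.
* The swap-polished projected-gradient splitter is a heuristic for an
  NP-hard partition problem; it is validated against random-split
  distributions, not against a global optimum.
* The deep-learning families are compact R implementations suitable
  for hundreds of features, not GPU-scale replacements.
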