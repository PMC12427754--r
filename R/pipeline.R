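#' Run the full detection-and-attribution pipeline on a cohort
#'
#' Convenience driver chaining every stage: exclusion of flagged
#' controls, three-stage feature selection, covariate-balanced
#' train/test split, per-family tuning and fitting with leak-proof
#' in-fold resampling, test-set evaluation, Shapley attribution with
#' adaptive outlier filtering, and the AUC-weighted consensus ranking.
#'
#' @param cohort A `synthetic_cohort` (or list with `expression` and
#'   `metadata` in the same shape).
#' @param families Model families to train (subset of NN, DNN, XGB,
#'   SVM, RF, LR, DT).
#' @param seed Master seed used for feature selection, the split, and
#'   model seeds.
#' @param fdr,cap,r_threshold,discovery_fraction Feature-selection
#'   parameters (see [select_features()]).
#' @param test_fraction Test share for [optimize_split()].
#' @param n_baseline Baseline random splits recorded by the splitter.
#' @param n_search_iters Randomized-search budget per family (NULL =
#'   family defaults).
#' @param cv_folds Cross-validation folds.
#' @param consensus_exclude Families excluded from the consensus
#'   aggregation.
#' @param attribution_on `"test"` (default) or `"train"`: samples the
#'   attributions are computed on.
#' @return List with `features` (selection report), `split`, `models`
#'   (per family: model, metrics, attributions, importance) and
#'   `consensus`.
#' @export
run_pipeline <- function(cohort, families = c("LR", "XGB"), seed = 1L,
                         fdr = 0.001, cap = 300L, r_threshold = 0.8,
                         discovery_fraction = 0.33, test_fraction = 0.2,
                         n_baseline = 0L, n_search_iters = NULL,
                         cv_folds = 5L, consensus_exclude = "DT",
                         attribution_on = c("test", "train")) {
  attribution_on <- match.arg(attribution_on)
  meta <- exclude_flagged(cohort$metadata)
  expr <- cohort$expression[meta$sample_id, , drop = FALSE]

  features <- select_features(expr, meta, discovery_fraction, fdr, cap,
                              r_threshold, seed = seed)
  genes <- features$retained
  if (!length(genes)) stop("feature selection retained no genes")

  split <- optimize_split(meta, test_fraction = test_fraction, seed = seed,
                          n_baseline = n_baseline)
  tr <- expr[split$train_ids, genes, drop = FALSE]
  te <- expr[split$test_ids, genes, drop = FALSE]
  ytr <- meta$label[match(split$train_ids, meta$sample_id)]
  yte <- meta$label[match(split$test_ids, meta$sample_id)]

  models <- list()
  for (fam in families) {
    cfg <- model_config(fam, n_search_iters = n_search_iters,
                        cv_folds = cv_folds, seed = seed + 41L)
    fit <- tune_and_fit(build_model(cfg), tr, ytr)
    scores <- predict(fit, te, type = "prob")
    calls <- as.numeric(scores >= fit$threshold)
    metrics <- classification_metrics(
      confusion_from_predictions(calls, yte), scores, yte)
    bg <- select_background(tr, fam, seed = seed)
    Xexpl <- if (attribution_on == "test") te else tr
    att <- compute_attributions(fit, Xexpl, bg, seed = seed)
    att <- filter_outliers(att)
    models[[fam]] <- list(model = fit, scores = scores, calls = calls,
                          metrics = metrics, attributions = att,
                          importance = global_importance(att))
  }

  importances <- lapply(models, `[[`, "importance")
  aucs <- vapply(models, function(m) m$metrics$auc, numeric(1))
  consensus <- if (length(setdiff(families, consensus_exclude)))
    weighted_consensus(importances, aucs, exclude = consensus_exclude)
  else NULL

  list(features = features, split = split, models = models,
       consensus = consensus, metadata = meta,
       genes = genes)
}

#' Evaluate trained pipeline models on a harmonized external cohort
#'
#' Applies [harmonize_external()] and recomputes scores, metrics,
#' attributions and the consensus ranking on the external samples using
#' the primary-trained models. Models whose genes are not fully covered
#' by the external gene set are skipped with a warning.
#'
#' @param result A [run_pipeline()] result.
#' @param external External cohort (list with `expression`,
#'   `metadata`).
#' @param overlap_ids Sample ids shared with the primary cohort
#'   (removed before evaluation).
#' @param consensus_exclude Families excluded from the consensus.
#' @return List with `metrics`, `consensus` and per-model details.
#' @export
evaluate_external <- function(result, external,
                              overlap_ids = character(0),
                              consensus_exclude = "DT") {
  models <- list()
  for (fam in names(result$models)) {
    fit <- result$models[[fam]]$model
    genes <- fit$classifier$genes
    common <- intersect(genes, colnames(external$expression))
    if (length(common) < length(genes)) {
      warning("external cohort lacks ", length(genes) - length(common),
              " genes of the ", fam, " model; skipping")
      next
    }
    keep <- !(rownames(external$expression) %in% overlap_ids)
    Xe <- external$expression[keep, genes, drop = FALSE]
    ye <- external$metadata$label[match(rownames(Xe),
                                        external$metadata$sample_id)]
    scores <- predict(fit, Xe, type = "prob")
    calls <- as.numeric(scores >= fit$threshold)
    metrics <- classification_metrics(
      confusion_from_predictions(calls, ye), scores, ye)
    att <- compute_attributions(fit, Xe,
                                select_background(Xe, fam, seed = 1L))
    att <- filter_outliers(att)
    models[[fam]] <- list(metrics = metrics, attributions = att,
                          importance = global_importance(att))
  }
  if (!length(models)) stop("no model could be evaluated externally")
  importances <- lapply(models, `[[`, "importance")
  aucs <- vapply(models, function(m) m$metrics$auc, numeric(1))
  consensus <- weighted_consensus(importances, aucs,
                                  exclude = consensus_exclude)
  list(models = models, consensus = consensus)
}
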