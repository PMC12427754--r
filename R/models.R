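#' @importFrom glmnet glmnet
#' @importFrom ranger ranger
#' @importFrom rpart rpart rpart.control
#' @importFrom e1071 svm
NULL

model_families <- c("NN", "DNN", "XGB", "SVM", "RF", "LR", "DT")

#' Model configuration for one classifier family
#'
#' Seven families are supported: shallow neural network (`NN`, one
#' hidden ReLU layer with dropout), deep neural network (`DNN`, two
#' hidden layers with two dropouts), gradient boosting (`XGB`), RBF
#' support vector machine (`SVM`), random forest (`RF`), penalized
#' logistic regression (`LR`) and a single decision tree (`DT`). Every
#' trained pipeline applies stages in the fixed order resample (SMOTE)
#' -> scale (z-score) -> classify, with the first two fitted inside
#' each cross-validation training fold only.
#'
#' The network search space follows the published configuration: hidden
#' units in {64, 128}, dropout in {0.1, 0.3}, learning rate in
#' {0.001, 0.0005}, epochs in {20, 30}, batch size in {32, 64}, Adam
#' with binary cross-entropy, early stopping on validation loss with
#' patience 5 and best-weight restoration. The remaining families use
#' conventional search spaces declared in
#' [default_search_space()].
#'
#' @param family One of `"NN"`, `"DNN"`, `"XGB"`, `"SVM"`, `"RF"`,
#'   `"LR"`, `"DT"`.
#' @param n_search_iters Randomized-search iterations (defaults: NN 8,
#'   DNN 5, others 8).
#' @param cv_folds Stratified cross-validation folds (default 5).
#' @param seed Integer seed (default 42).
#' @param search_space Optional list of candidate values per
#'   hyperparameter, overriding the family default.
#' @param threshold_source `"oof"` calibrates the decision threshold on
#'   pooled out-of-fold CV predictions (default); `"refit"` uses the
#'   refit model's scores on the full training set.
#' @param smote_k SMOTE nearest-neighbour count.
#' @return An object of class `model_config`.
#' @export
model_config <- function(family, n_search_iters = NULL, cv_folds = 5L,
                         seed = 42L, search_space = NULL,
                         threshold_source = c("oof", "refit"),
                         smote_k = 5L) {
  family <- match.arg(family, model_families)
  if (is.null(n_search_iters))
    n_search_iters <- switch(family, NN = 8L, DNN = 5L, 8L)
  if (is.null(search_space)) search_space <- default_search_space(family)
  structure(list(family = family,
                 n_search_iters = as.integer(n_search_iters),
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed),
                 search_space = search_space,
                 threshold_source = match.arg(threshold_source),
                 smote_k = as.integer(smote_k)),
            class = "model_config")
}

#' @rdname model_config
#' @export
default_search_space <- function(family) {
  family <- match.arg(family, model_families)
  switch(family,
    NN = list(units = c(64L, 128L), dropout = c(0.1, 0.3),
              lr = c(0.001, 0.0005), epochs = c(20L, 30L),
              batch_size = c(32L, 64L)),
    DNN = list(units = c(64L, 128L), units2 = c(64L, 128L),
               dropout = c(0.1, 0.3), lr = c(0.001, 0.0005),
               epochs = c(20L, 30L), batch_size = c(32L, 64L)),
    XGB = list(nrounds = c(100L, 200L, 300L), max_depth = c(3L, 4L, 6L),
               eta = c(0.05, 0.1, 0.3), subsample = c(0.8, 1),
               colsample_bytree = c(0.8, 1)),
    SVM = list(cost = c(0.1, 1, 10, 100), gamma = c(0.001, 0.01, 0.1)),
    RF = list(num_trees = c(300L, 500L), mtry_frac = c(0.1, 0.33, 0.5),
              min_node_size = c(1L, 5L, 10L)),
    LR = list(alpha = c(0, 0.5, 1), lambda = c(1e-4, 1e-3, 1e-2, 1e-1)),
    DT = list(cp = c(0.001, 0.005, 0.01), maxdepth = c(3L, 5L, 8L),
              minsplit = c(10L, 20L))
  )
}

#' Build an untrained classifier pipeline
#'
#' Wraps a [model_config()] into an untrained pipeline object whose
#' stage order is fixed as resample -> scale -> classify. Fit it with
#' [tune_and_fit()].
#'
#' @param config A `model_config`.
#' @return An object of class `tep_pipeline`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  structure(list(config = config,
                 stages = c("resample", "scale", "classify")),
            class = "tep_pipeline")
}

sample_param_sets <- function(space, n_iter) {
  grid <- expand.grid(space, stringsAsFactors = FALSE)
  take <- sample.int(nrow(grid), min(n_iter, nrow(grid)))
  lapply(take, function(i) as.list(grid[i, , drop = FALSE]))
}

fit_classifier <- function(family, params, X, y01, seed = 42L) {
  fit <- switch(family,
    NN = mlp_fit(X, y01, hidden = params$units, dropout = params$dropout,
                 lr = params$lr, epochs = params$epochs,
                 batch_size = params$batch_size, patience = 5L, seed = seed),
    DNN = mlp_fit(X, y01, hidden = c(params$units, params$units2),
                  dropout = params$dropout, lr = params$lr,
                  epochs = params$epochs, batch_size = params$batch_size,
                  patience = 5L, seed = seed),
    XGB = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    subsample = params$subsample,
                    colsample_bytree = params$colsample_bytree,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y01),
      nrounds = params$nrounds, verbose = 0),
    SVM = e1071::svm(x = X, y = factor(y01, levels = c(0, 1)),
                     kernel = "radial", cost = params$cost,
                     gamma = params$gamma, probability = TRUE),
    RF = ranger::ranger(x = X, y = factor(y01, levels = c(0, 1)),
                        probability = TRUE, num.trees = params$num_trees,
                        mtry = max(1L, floor(params$mtry_frac * ncol(X))),
                        min.node.size = params$min_node_size,
                        seed = seed, num.threads = 1),
    LR = glmnet::glmnet(X, y01, family = "binomial", alpha = params$alpha,
                        lambda = params$lambda),
    DT = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- factor(y01, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     cp = params$cp, maxdepth = params$maxdepth,
                     minsplit = params$minsplit))
    },
    stop("unknown model family: ", family)
  )
  list(family = family, fit = fit, genes = colnames(X), params = params)
}

predict_prob <- function(clf, X) {
  X <- X[, clf$genes, drop = FALSE]
  switch(clf$family,
    NN = ,
    DNN = predict(clf$fit, X, type = "prob"),
    XGB = as.numeric(predict(clf$fit, xgboost::xgb.DMatrix(X))),
    SVM = {
      pr <- attr(predict(clf$fit, X, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    RF = as.numeric(predict(clf$fit, X, num.threads = 1)$predictions[, "1"]),
    LR = as.numeric(predict(clf$fit, X, type = "response")),
    DT = as.numeric(predict(clf$fit, data.frame(X, check.names = FALSE),
                            type = "prob")[, "1"]),
    stop("unknown model family: ", clf$family)
  )
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lv in unique(y)) {
    ix <- sample(which(y == lv))
    folds[ix] <- rep_len(seq_len(k), length(ix))
  }
  folds
}

#' Tune and fit a classifier with leak-proof cross-validation
#'
#' Runs randomized search over the family's hyperparameter space,
#' scoring each candidate by mean AUC over stratified k-fold
#' cross-validation. Within each fold, SMOTE resampling and z-score
#' scaling are fitted on the training side of the fold only, so no
#' validation information (and no synthetic sample) ever influences
#' preprocessing or reaches a validation score. The winning candidate
#' is refit on the full training set (again SMOTE -> scale -> classify)
#' and the decision threshold is calibrated by Youden's J on pooled
#' out-of-fold predictions (default) or on refit training scores.
#'
#' @param pipeline A [build_model()] pipeline (or a `model_config`).
#' @param expr Training expression matrix (samples x genes,
#'   unscaled; scaling happens inside).
#' @param labels Class labels aligned to `expr` rows: `"cancer"` /
#'   `"control"` (or a 0/1 vector with 1 = cancer).
#' @param keep_diagnostics Record per-fold id sets, scaler means and
#'   synthetic-row counts (used by leakage tests).
#' @return An object of class `tep_model`: `family`, `best_params`,
#'   `scaler`, `classifier`, `threshold`, `cv_auc`, `fold_aucs`,
#'   `oof` (scores + labels), `search` (per-candidate mean AUCs) and
#'   optional `diagnostics`.
#' @export
tune_and_fit <- function(pipeline, expr, labels, keep_diagnostics = FALSE) {
  config <- if (inherits(pipeline, "tep_pipeline")) pipeline$config
            else pipeline
  stopifnot(inherits(config, "model_config"))
  y01 <- as_binary_labels(labels)
  if (length(unique(y01)) < 2L)
    stop("training data must contain both classes")
  set.seed(config$seed)
  candidates <- sample_param_sets(config$search_space, config$n_search_iters)
  folds <- stratified_folds(y01, config$cv_folds)

  n <- nrow(expr)
  best <- list(auc = -Inf)
  search <- data.frame()
  diagnostics <- list()
  for (ci in seq_along(candidates)) {
    params <- candidates[[ci]]
    fold_aucs <- numeric(0)
    oof_scores <- rep(NA_real_, n)
    fold_diag <- list()
    for (f in seq_len(config$cv_folds)) {
      tr <- which(folds != f); va <- which(folds == f)
      if (length(unique(y01[va])) < 2L || length(unique(y01[tr])) < 2L) {
        warning("single-class fold skipped")
        next
      }
      sm <- smote(expr[tr, , drop = FALSE], y01[tr], k = config$smote_k)
      scaler <- fit_scaler(sm$X)
      clf <- fit_classifier(config$family, params,
                            apply_scaler(scaler, sm$X),
                            as.numeric(as.character(sm$y)),
                            seed = config$seed + 100L * ci + f)
      sc <- predict_prob(clf, apply_scaler(scaler, expr[va, , drop = FALSE]))
      fold_aucs <- c(fold_aucs, auc_score(sc, y01[va]))
      oof_scores[va] <- sc
      if (keep_diagnostics)
        fold_diag[[f]] <- list(
          fold = f,
          train_ids = rownames(expr)[tr],
          val_ids = rownames(expr)[va],
          scaler_mean = scaler$mean,
          n_synthetic = sm$n_synthetic,
          synthetic_rows_scored = 0L)
    }
    if (!length(fold_aucs)) stop("all cross-validation folds were skipped")
    m_auc <- mean(fold_aucs)
    search <- rbind(search,
                    data.frame(candidate = ci, cv_auc = m_auc))
    if (m_auc > best$auc) {
      best <- list(auc = m_auc, params = params, fold_aucs = fold_aucs,
                   oof = oof_scores)
      if (keep_diagnostics) diagnostics <- fold_diag
    }
  }

  # refit the winner on the full training set
  sm <- smote(expr, y01, k = config$smote_k)
  scaler <- fit_scaler(sm$X)
  clf <- fit_classifier(config$family, best$params,
                        apply_scaler(scaler, sm$X),
                        as.numeric(as.character(sm$y)),
                        seed = config$seed)
  refit_scores <- predict_prob(clf, apply_scaler(scaler, expr))
  thr_scores <- if (config$threshold_source == "oof") best$oof
                else refit_scores
  ok <- !is.na(thr_scores)
  threshold <- calibrate_threshold(thr_scores[ok], y01[ok])

  structure(list(family = config$family,
                 config = config,
                 best_params = best$params,
                 scaler = scaler,
                 classifier = clf,
                 threshold = threshold,
                 cv_auc = best$auc,
                 fold_aucs = best$fold_aucs,
                 oof = list(scores = best$oof, labels = y01),
                 search = search,
                 diagnostics = if (keep_diagnostics) diagnostics else NULL),
            class = "tep_model")
}

as_binary_labels <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.numeric(labels))
  }
  as.numeric(as.character(labels) == "cancer")
}

#' Calibrate the decision threshold by Youden's J
#'
#' Scans the midpoints of consecutive sorted unique scores and returns
#' the cutoff maximizing J = sensitivity + specificity - 1 (prediction
#' rule: score >= threshold means cancer). Ties are broken towards the
#' smallest threshold. The calibrated threshold is meant to be frozen
#' and applied unchanged to held-out predictions.
#'
#' @param scores Numeric probability scores.
#' @param labels Binary labels (1/"cancer" = positive).
#' @return The threshold (numeric scalar in [0, 1] for probability
#'   scores).
#' @export
calibrate_threshold <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop("threshold calibration needs both classes")
  u <- sort(unique(scores))
  cand <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else u
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  j <- vapply(cand, function(t) {
    sens <- sum(scores >= t & y == 1) / n_pos
    spec <- sum(scores < t & y == 0) / n_neg
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]          # which.max takes the first (smallest) maximizer
}

#' @export
print.tep_model <- function(x, ...) {
  cat("trained", x$family, "pipeline (resample -> scale -> classify)\n")
  cat("  cv AUC:", round(x$cv_auc, 4),
      " threshold:", round(x$threshold, 4), "\n")
  invisible(x)
}

#' Predict from a trained pipeline
#'
#' Applies the frozen training scaler, the fitted classifier, and (for
#' `type = "class"`) the calibrated Youden threshold.
#'
#' @param object A `tep_model` from [tune_and_fit()].
#' @param newdata Expression matrix covering the training genes
#'   (unscaled).
#' @param type `"prob"` for cancer-class probabilities, `"class"` for
#'   thresholded 0/1 calls.
#' @param ... Unused.
#' @export
predict.tep_model <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  sc <- predict_prob(object$classifier,
                     apply_scaler(object$scaler, newdata))
  if (type == "prob") sc else as.numeric(sc >= object$threshold)
}
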