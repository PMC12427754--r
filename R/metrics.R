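#' Confusion-matrix counts
#'
#' Either construct directly from counts or tabulate from thresholded
#' predictions and labels (positive class = cancer = 1).
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param predictions 0/1 predicted classes.
#' @param labels 0/1 (or cancer/control) true labels.
#' @export
confusion_from_predictions <- function(predictions, labels) {
  y <- as_binary_labels(labels)
  p <- as.numeric(predictions)
  confusion_counts(tp = sum(p == 1 & y == 1), tn = sum(p == 0 & y == 0),
                   fp = sum(p == 1 & y == 0), fn = sum(p == 0 & y == 1))
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' Probability that a random positive outranks a random negative, with
#' ties counted one half; equal to the area under the ROC curve.
#'
#' @param scores Numeric scores (higher = more cancer-like).
#' @param labels Binary labels (1 = cancer).
#' @return AUC in [0, 1], or `NA` if a class is empty.
#' @export
auc_score <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise sum of precision increments over descending-score
#' thresholds: AP = sum_k (R_k - R_{k-1}) P_k, with tied scores grouped
#' into a single threshold step.
#'
#' @inheritParams auc_score
#' @return AP in [0, 1], or `NA` if no positives.
#' @export
average_precision <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1)
  if (n_pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  tp <- cumsum(yy); fp <- cumsum(1 - yy)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_tie]; fp <- fp[last_of_tie]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Full classification report
#'
#' Point metrics derived from the confusion matrix (sensitivity,
#' specificity, precision, accuracy, F1, balanced accuracy) plus the
#' ranking metrics AUC and average precision when scores are supplied.
#' Metrics whose denominator is empty are reported as `NA` and listed
#' in the `undefined` field rather than silently set to 0.
#'
#' @param cm A `confusion_counts`.
#' @param scores Optional probability scores for AUC/AP.
#' @param labels Labels aligned to `scores`.
#' @return An object of class `metrics_report` (a named list).
#' @examples
#' classification_metrics(confusion_counts(tp = 300, tn = 53,
#'                                         fp = 25, fn = 27))
#' @export
classification_metrics <- function(cm, scores = NULL, labels = NULL) {
  stopifnot(inherits(cm, "confusion_counts"))
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  sens <- safe_div(cm$tp, cm$tp + cm$fn)
  spec <- safe_div(cm$tn, cm$tn + cm$fp)
  prec <- safe_div(cm$tp, cm$tp + cm$fp)
  acc <- safe_div(cm$tp + cm$tn, n)
  f1 <- safe_div(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn)
  bal <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  auc <- ap <- NA_real_
  if (!is.null(scores)) {
    auc <- auc_score(scores, labels)
    ap <- average_precision(scores, labels)
  }
  out <- list(auc = auc, ap = ap, sensitivity = sens, specificity = spec,
              precision = prec, f1 = f1, accuracy = acc,
              balanced_accuracy = bal, confusion = cm)
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "precision", "f1", "accuracy",
          "balanced_accuracy")], is.na, logical(1))))
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  v <- unlist(x[c("auc", "ap", "sensitivity", "specificity", "precision",
                  "f1", "accuracy", "balanced_accuracy")])
  print(round(v, digits))
  invisible(x)
}

#' Stratified detection accuracy
#'
#' Per-stratum recall among cancer samples (detection rate by stage or
#' by cancer type); control samples form their own stratum scored as
#' the correct-rejection rate (specificity restricted to controls).
#'
#' @param predictions 0/1 predicted classes (1 = cancer call).
#' @param metadata Metadata aligned to `predictions`, with `label` and
#'   the stratum column.
#' @param stratum `"stage"` or `"cancer_type"` (any metadata column).
#' @return data.frame with columns stratum, n, accuracy (NA-flagged for
#'   empty strata).
#' @export
stratified_accuracy <- function(predictions, metadata, stratum = "stage") {
  if (!stratum %in% names(metadata))
    stop("metadata lacks the stratum column '", stratum, "'")
  p <- as.numeric(predictions)
  is_cancer <- metadata$label == "cancer"
  strata <- ifelse(is_cancer, as.character(metadata[[stratum]]), "control")
  lv <- sort(unique(strata))
  acc <- vapply(lv, function(s) {
    ix <- strata == s
    if (!any(ix)) return(NA_real_)
    if (s == "control") mean(p[ix] == 0) else mean(p[ix] == 1)
  }, numeric(1))
  data.frame(stratum = lv, n = as.integer(table(factor(strata, lv))),
             accuracy = acc, row.names = NULL)
}

#' Cross-model average of stratified accuracies
#'
#' Unweighted mean of per-model stratum accuracies, aligning strata by
#' name.
#'
#' @param tables List of data.frames from [stratified_accuracy()], one
#'   per model.
#' @return data.frame with stratum and mean accuracy.
#' @export
cross_model_stratified <- function(tables) {
  lv <- sort(unique(unlist(lapply(tables, `[[`, "stratum"))))
  mat <- vapply(tables, function(tb)
    tb$accuracy[match(lv, tb$stratum)], numeric(length(lv)))
  mat <- matrix(mat, nrow = length(lv))
  data.frame(stratum = lv, accuracy = rowMeans(mat, na.rm = TRUE),
             row.names = NULL)
}
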