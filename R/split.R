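#' Covariate divergence of a (soft) train/test assignment
#'
#' The balance objective minimized by [optimize_split()]. Given
#' per-sample test-membership weights in [0, 1], it sums, over the
#' categorical covariates sex, cancer type, institution and the class
#' label, the squared differences between weighted test-side and
#' train-side category proportions, and adds the squared standardized
#' difference of the weighted age means. The value is 0 iff all
#' compared summaries coincide, and is smooth in the weights, which
#' makes it amenable to gradient-based constrained optimization.
#'
#' @param metadata Metadata data.frame with columns `label`, `sex`,
#'   `cancer_type`, `institution`, `age`.
#' @param weights Numeric vector in [0, 1], one per row of `metadata`;
#'   1 = test side, 0 = train side.
#' @return A single non-negative number.
#' @export
split_divergence <- function(metadata, weights) {
  dv <- divergence_internal(metadata, weights, gradient = FALSE)
  dv$value
}

split_covariates <- c("label", "sex", "cancer_type", "institution")

divergence_internal <- function(metadata, weights, gradient = FALSE) {
  n <- nrow(metadata)
  stopifnot(length(weights) == n)
  if (any(weights < -1e-9 | weights > 1 + 1e-9))
    stop("weights must lie in [0, 1]")
  w <- pmin(pmax(weights, 0), 1)
  s <- sum(w)
  if (s <= 0 || s >= n)
    stop("degenerate assignment: one side of the split is empty")
  grad <- if (gradient) numeric(n) else NULL
  value <- 0
  for (cov in split_covariates) {
    f <- factor(metadata[[cov]])
    k <- nlevels(f)
    a <- rowsum(w, f)[, 1L]                    # weighted count per category
    n_c <- tabulate(f, k)
    p_test <- a / s
    p_train <- (n_c - a) / (n - s)
    d <- p_test - p_train
    value <- value + sum(d^2)
    if (gradient) {
      # d p_test,c / d w_i = (1{i in c} - p_test,c) / s
      # d p_train,c / d w_i = -(1{i in c} - p_train,c) / (n - s)
      ind_term <- (2 * d / s + 2 * d / (n - s))[as.integer(f)]
      const_term <- sum(2 * d * (-p_test / s - p_train / (n - s)))
      grad <- grad + ind_term + const_term
    }
  }
  age <- metadata$age
  sd_age <- stats::sd(age)
  if (sd_age > 0) {
    mu_t <- sum(w * age) / s
    mu_tr <- sum((1 - w) * age) / (n - s)
    z <- (mu_t - mu_tr) / sd_age
    value <- value + z^2
    if (gradient) {
      dmu <- (age - mu_t) / s + (age - mu_tr) / (n - s)
      grad <- grad + 2 * z / sd_age * dmu
    }
  }
  list(value = value, grad = grad)
}

# Euclidean projection onto {w in [0,1]^n : sum(w) = m} by bisection on the
# shift tau in clamp(w - tau, 0, 1).
project_capped_simplex <- function(w, m) {
  f <- function(tau) sum(pmin(pmax(w - tau, 0), 1)) - m
  lo <- min(w) - 1; hi <- max(w)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  pmin(pmax(w - (lo + hi) / 2, 0), 1)
}

# label-stratified random hard split of exactly m test samples
stratified_hard_split <- function(labels, m) {
  n <- length(labels)
  per <- table(labels) * m / n
  take <- floor(per)
  rem <- m - sum(take)
  if (rem > 0) {
    extra <- order(per - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1
  }
  w <- numeric(n)
  for (lv in names(take)) {
    ix <- which(labels == lv)
    w[sample(ix, min(take[[lv]], length(ix)))] <- 1
  }
  # adjust in the rare case strata were too small
  d <- m - sum(w)
  if (d > 0) w[sample(which(w == 0), d)] <- 1
  if (d < 0) w[sample(which(w == 1), -d)] <- 0
  w
}

#' Covariate-balanced train/test partition by constrained optimization
#'
#' Splits the cohort into train and test sets of exact sizes while
#' minimizing [split_divergence()] over age, sex, cancer type,
#' institution and class label. The combinatorial problem is relaxed to
#' continuous per-sample test-membership weights in [0, 1] under the
#' equality constraint that the weights sum to the test-set size; the
#' relaxation is solved by projected gradient descent with analytic
#' gradients and backtracking line search from a label-stratified random
#' start, and the solution is rounded by taking the largest weights as
#' the test set (ties broken by sample-id order). The divergence is then
#' recomputed on the discrete split. If the optimized split is no better
#' than its stratified starting point, the starting point is kept and a
#' warning notes the fallback.
#'
#' For context, the divergences of `n_baseline` label-stratified random
#' splits are recorded, giving a null distribution against which the
#' optimized balance can be judged.
#'
#' @param metadata Sample metadata (see [split_divergence()]); must
#'   contain a `sample_id` column.
#' @param test_fraction Fraction of samples assigned to the test set.
#'   The test size is `round(test_fraction * n)` (round-half-even).
#' @param seed Integer seed (initialization and baselines).
#' @param n_baseline Number of random baseline splits (0 to skip).
#' @param test_n Optional explicit test-set size overriding
#'   `test_fraction`.
#' @param max_iter Projected-gradient iteration budget.
#' @return An object of class `split_result`: `train_ids`, `test_ids`,
#'   `divergence` (discrete), `balance_table` (per-covariate train vs
#'   test summaries), `baseline_divergences`.
#' @export
optimize_split <- function(metadata, test_fraction = 0.2, seed = 1L,
                           n_baseline = 1000L, test_n = NULL,
                           max_iter = 200L) {
  n <- nrow(metadata)
  if (n < 10L) stop("need at least 10 samples to split")
  m <- if (is.null(test_n)) round(test_fraction * n) else as.integer(test_n)
  if (m < 2L) stop("test_fraction yields a test set smaller than 2")
  if (m >= n - 1L) stop("test set leaves no training samples")
  set.seed(seed)

  w0 <- stratified_hard_split(metadata$label, m)
  init_value <- split_divergence(metadata, w0)

  # projected gradient on the continuous relaxation
  w <- project_capped_simplex(w0 + stats::rnorm(n, 0, 0.05), m)
  step <- 1
  cur <- divergence_internal(metadata, w, gradient = TRUE)
  for (it in seq_len(max_iter)) {
    cand <- project_capped_simplex(w - step * cur$grad, m)
    cv <- divergence_internal(metadata, cand, gradient = FALSE)
    if (cv$value < cur$value - 1e-14) {
      w <- cand
      cur <- divergence_internal(metadata, w, gradient = TRUE)
      step <- step * 1.5
    } else {
      step <- step / 2
      if (step < 1e-10) break
    }
  }
  # round: top-m weights, ties by sample-id order
  ord <- order(-w, metadata$sample_id)
  hard <- numeric(n); hard[ord[seq_len(m)]] <- 1
  # discrete polish: sampled pairwise swaps with incremental evaluation
  hard <- refine_swaps(metadata, hard, n_swaps = 50L * n)
  opt_value <- split_divergence(metadata, hard)

  if (opt_value > init_value) {
    warning("optimizer did not improve on the stratified start; keeping the start")
    hard <- w0
    opt_value <- init_value
  }

  baselines <- numeric(0)
  if (n_baseline > 0L) {
    baselines <- vapply(seq_len(n_baseline), function(i) {
      split_divergence(metadata, stratified_hard_split(metadata$label, m))
    }, numeric(1))
  }

  test_ids <- metadata$sample_id[hard == 1]
  train_ids <- metadata$sample_id[hard == 0]
  structure(list(
    train_ids = train_ids,
    test_ids = test_ids,
    divergence = opt_value,
    balance_table = balance_table(metadata, hard),
    baseline_divergences = baselines
  ), class = "split_result")
}

# Hill-climb on the discrete split: randomly sampled test/train swaps,
# accepted when they reduce the divergence. The objective depends on the
# assignment only through per-category test-side counts and the test-side
# age sum, so each candidate swap is evaluated incrementally in O(#levels).
refine_swaps <- function(metadata, hard, n_swaps = 20000L) {
  n <- nrow(metadata)
  m <- sum(hard)
  covs <- lapply(split_covariates, function(cv) {
    f <- factor(metadata[[cv]])
    list(idx = as.integer(f), n_c = tabulate(f, nlevels(f)))
  })
  age <- metadata$age
  sd_age <- stats::sd(age)
  counts <- lapply(covs, function(cv)
    vapply(seq_along(cv$n_c), function(c)
      sum(hard[cv$idx == c]), numeric(1)))
  age_sum <- sum(age[hard == 1]); age_tot <- sum(age)
  val <- function(counts, age_sum) {
    v <- 0
    for (ci in seq_along(covs)) {
      a <- counts[[ci]]; n_c <- covs[[ci]]$n_c
      v <- v + sum((a / m - (n_c - a) / (n - m))^2)
    }
    if (sd_age > 0)
      v <- v + ((age_sum / m - (age_tot - age_sum) / (n - m)) / sd_age)^2
    v
  }
  cur <- val(counts, age_sum)
  test_ix <- which(hard == 1); train_ix <- which(hard == 0)
  for (it in seq_len(n_swaps)) {
    ti <- sample.int(m, 1L); tj <- sample.int(n - m, 1L)
    i <- test_ix[ti]; j <- train_ix[tj]
    new_counts <- counts
    for (ci in seq_along(covs)) {
      idx <- covs[[ci]]$idx
      new_counts[[ci]][idx[i]] <- new_counts[[ci]][idx[i]] - 1
      new_counts[[ci]][idx[j]] <- new_counts[[ci]][idx[j]] + 1
    }
    new_age <- age_sum - age[i] + age[j]
    nv <- val(new_counts, new_age)
    if (nv < cur - 1e-15) {
      counts <- new_counts; age_sum <- new_age; cur <- nv
      test_ix[ti] <- j; train_ix[tj] <- i
    }
  }
  out <- numeric(n); out[test_ix] <- 1
  out
}

balance_table <- function(metadata, w) {
  test <- metadata[w == 1, , drop = FALSE]
  train <- metadata[w == 0, , drop = FALSE]
  rows <- list()
  for (cov in split_covariates) {
    lv <- sort(unique(metadata[[cov]]))
    rows[[cov]] <- data.frame(
      covariate = cov, level = lv,
      train = as.numeric(table(factor(train[[cov]], lv)) / nrow(train)),
      test = as.numeric(table(factor(test[[cov]], lv)) / nrow(test)))
  }
  rows$age <- data.frame(
    covariate = "age", level = c("mean", "sd"),
    train = c(mean(train$age), stats::sd(train$age)),
    test = c(mean(test$age), stats::sd(test$age)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.split_result <- function(x, ...) {
  cat("covariate-balanced split:", length(x$train_ids), "train /",
      length(x$test_ids), "test\n")
  cat("  divergence:", signif(x$divergence, 4))
  if (length(x$baseline_divergences))
    cat("  (median of", length(x$baseline_divergences), "random splits:",
        signif(stats::median(x$baseline_divergences), 4), ")")
  cat("\n")
  invisible(x)
}
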