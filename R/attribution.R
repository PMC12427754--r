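#' Choose the background dataset for attribution
#'
#' Exact and gradient backends (gradient boosting, logistic regression,
#' neural networks) use the entire training set as background. The
#' families explained through the sampling-based kernel backend (SVM,
#' random forest, decision tree) are costly to evaluate, so a
#' representative subset of `k` training samples is selected via
#' k-means clustering (the sample nearest each centroid). If the
#' training set is smaller than `k`, the full set is used with a
#' warning.
#'
#' @param train Training expression matrix (unscaled, samples x genes).
#' @param model_family One of the seven family codes.
#' @param k Number of cluster representatives for kernel-backend
#'   families.
#' @param seed Seed for k-means.
#' @return The background matrix, with attribute `background_spec`
#'   (`"full_train"` or `"k_representatives"`).
#' @export
select_background <- function(train, model_family, k = 50L, seed = 1L) {
  stopifnot(nrow(train) > 0)
  if (!model_family %in% kernel_backend_families) {
    attr(train, "background_spec") <- "full_train"
    return(train)
  }
  if (nrow(train) < k) {
    warning("training set smaller than ", k,
            " samples; using the full set as kernel background")
    attr(train, "background_spec") <- "full_train"
    return(train)
  }
  set.seed(seed)
  km <- stats::kmeans(train, centers = k, iter.max = 50, nstart = 1)
  reps <- vapply(seq_len(k), function(ci) {
    ix <- which(km$cluster == ci)
    d <- rowSums((train[ix, , drop = FALSE] -
                    matrix(km$centers[ci, ], length(ix), ncol(train),
                           byrow = TRUE))^2)
    ix[which.min(d)]
  }, integer(1))
  bg <- train[reps, , drop = FALSE]
  attr(bg, "background_spec") <- "k_representatives"
  bg
}

kernel_backend_families <- c("SVM", "RF", "DT")

#' Shapley attributions for the cancer class
#'
#' Computes per-sample, per-gene signed Shapley attributions of the
#' trained pipeline's cancer-class output, with the backend chosen by
#' model family:
#' * `LR` - closed-form linear attribution on the log-odds scale:
#'   `phi_j = beta_j (z_j - mean(z_bg,j))` in scaled coordinates.
#' * `XGB` - exact tree-path attribution (native TreeSHAP), log-odds
#'   scale.
#' * `NN`, `DNN` - integrated gradients of the pre-sigmoid output,
#'   averaged over background samples (expected-gradients style).
#' * `SVM`, `RF`, `DT` - sampling-based kernel Shapley regression on
#'   the probability output; evaluation is limited to `max_eval`
#'   samples (extra rows are dropped with a warning).
#'
#' For the additive-exact backends (`LR`, `XGB`) the per-sample
#' attribution sum plus the base value reproduces the model's margin.
#'
#' @param model A `tep_model` from [tune_and_fit()].
#' @param X Expression matrix to explain (unscaled, covering the
#'   model's genes).
#' @param background Background matrix from [select_background()]
#'   (unscaled).
#' @param max_eval Sample budget for the kernel backend.
#' @param nsim Coalition budget per sample for the kernel backend
#'   (exact enumeration is used when feasible).
#' @param ig_steps,ig_background Integration steps and background
#'   subsample size for the gradient backend.
#' @param seed Seed for coalition sampling.
#' @return An object of class `attribution_set`: `model_family`,
#'   `values` (samples x genes), `base_value`, `background_spec`,
#'   `output_scale`, plus `filtered_values`/`filter_report` after
#'   [filter_outliers()].
#' @export
compute_attributions <- function(model, X, background,
                                 max_eval = 50L, nsim = 512L,
                                 ig_steps = 20L, ig_background = 25L,
                                 seed = 1L) {
  stopifnot(inherits(model, "tep_model"))
  genes <- model$classifier$genes
  if (!all(genes %in% colnames(X)))
    stop("X does not cover the model's training genes")
  spec <- attr(background, "background_spec")
  if (is.null(spec)) spec <- "full_train"
  X <- X[, genes, drop = FALSE]
  background <- background[, genes, drop = FALSE]
  Z <- as.matrix(apply_scaler(model$scaler, X))
  B <- as.matrix(apply_scaler(model$scaler, background))
  fam <- model$family

  if (fam == "LR") {
    beta <- as.numeric(stats::coef(model$classifier$fit))[-1]
    a0 <- as.numeric(stats::coef(model$classifier$fit))[1]
    mu <- colMeans(B)
    vals <- sweep(Z, 2, mu, "-") * rep(beta, each = nrow(Z))
    base <- a0 + sum(beta * mu)
    scale <- "logit"
  } else if (fam == "XGB") {
    contrib <- predict(model$classifier$fit, xgboost::xgb.DMatrix(Z),
                       predcontrib = TRUE)
    vals <- contrib[, seq_along(genes), drop = FALSE]
    base <- contrib[1, ncol(contrib)]
    scale <- "logit"
  } else if (fam %in% c("NN", "DNN")) {
    att <- integrated_gradients(model$classifier$fit, Z, B,
                                steps = ig_steps,
                                n_background = ig_background, seed = seed)
    vals <- att$values
    base <- att$base_value
    scale <- "logit"
  } else if (fam %in% kernel_backend_families) {
    if (nrow(Z) > max_eval) {
      warning("kernel backend budget: explaining the first ", max_eval,
              " of ", nrow(Z), " samples")
      Z <- Z[seq_len(max_eval), , drop = FALSE]
    }
    f <- function(M) {
      colnames(M) <- genes
      predict_prob(model$classifier, M)
    }
    ks <- kernel_shap(f, Z, B, nsim = nsim, seed = seed)
    vals <- ks$values
    base <- ks$base_value
    scale <- "probability"
  } else stop("unknown model family: ", fam)

  dimnames(vals) <- list(rownames(Z), genes)
  structure(list(model_family = fam, values = vals, base_value = base,
                 background_spec = spec, output_scale = scale,
                 filtered_values = NULL, filter_report = NULL),
            class = "attribution_set")
}

# Expected-gradients attribution of the network's pre-sigmoid output:
# for each background sample b, integrate the input gradient along the
# straight path from b to x (trapezoid-free midpoint grid), multiply by
# (x - b), then average over backgrounds.
integrated_gradients <- function(mlp, Z, B, steps = 20L,
                                 n_background = 25L, seed = 1L) {
  set.seed(seed)
  if (nrow(B) > n_background)
    B <- B[sample.int(nrow(B), n_background), , drop = FALSE]
  alphas <- (seq_len(steps) - 0.5) / steps
  nb <- nrow(B)
  vals <- matrix(0, nrow(Z), ncol(Z))
  for (i in seq_len(nrow(Z))) {
    x <- Z[i, ]
    diffmat <- matrix(x, nb, length(x), byrow = TRUE) - B   # nb x p
    # all interpolation points for all backgrounds in one batch
    P <- do.call(rbind, lapply(alphas, function(a) B + a * diffmat))
    G <- mlp_input_gradient(mlp, P)
    avg_grad <- matrix(0, nb, ncol(Z))
    for (s in seq_len(steps)) {
      avg_grad <- avg_grad + G[((s - 1) * nb + 1):(s * nb), , drop = FALSE]
    }
    avg_grad <- avg_grad / steps
    vals[i, ] <- colMeans(diffmat * avg_grad)
  }
  base <- mean(predict(mlp, B, type = "logit"))
  list(values = vals, base_value = base)
}

# Kernel Shapley regression (Lundberg & Lee weighting). For each row of
# Z, coalition values v(S) are interventional: features outside S are
# replaced by background rows and predictions averaged. When full
# enumeration of the 2^p - 2 proper coalitions fits the budget, the
# exact weighted least squares is solved (recovering exact Shapley
# values of the interventional game); otherwise coalitions are sampled
# from the Shapley kernel distribution over sizes.
kernel_shap <- function(f, Z, B, nsim = 512L, seed = 1L) {
  set.seed(seed)
  p <- ncol(Z)
  nb <- nrow(B)
  base <- mean(f(B))
  n_all <- 2^p - 2
  exact <- is.finite(n_all) && n_all <= nsim
  if (exact) {
    Mz <- as.matrix(expand.grid(rep(list(0:1), p)))[-c(1, 2^p), , drop = FALSE]
    sizes <- rowSums(Mz)
    wts <- (p - 1) / (choose(p, sizes) * sizes * (p - sizes))
  } else {
    sz_support <- 1:(p - 1)
    sz_prob <- (p - 1) / (sz_support * (p - sz_support))
    sizes <- sample(sz_support, nsim, replace = TRUE,
                    prob = sz_prob / sum(sz_prob))
    Mz <- t(vapply(sizes, function(s) {
      z <- numeric(p); z[sample.int(p, s)] <- 1; z
    }, numeric(p)))
    wts <- rep(1, nsim)
  }
  nc <- nrow(Mz)
  vals <- matrix(0, nrow(Z), p)
  for (i in seq_len(nrow(Z))) {
    x <- Z[i, ]
    # evaluation matrix: for each coalition, nb rows mixing x and background
    big <- B[rep(seq_len(nb), nc), , drop = FALSE]
    zrep <- Mz[rep(seq_len(nc), each = nb), , drop = FALSE]
    xrep <- matrix(x, nrow(big), p, byrow = TRUE)
    big <- zrep * xrep + (1 - zrep) * big
    preds <- f(big)
    v <- rowsum(preds, rep(seq_len(nc), each = nb))[, 1] / nb
    fx <- f(matrix(x, 1, p))
    # constrained WLS: eliminate phi_p via the efficiency constraint
    y <- v - base - Mz[, p] * (fx - base)
    A <- Mz[, -p, drop = FALSE] - Mz[, p]
    WA <- A * wts
    phi_head <- tryCatch(
      solve(crossprod(A, WA), crossprod(WA, y)),
      error = function(e) qr.solve(crossprod(A, WA) +
                                     diag(1e-10, p - 1), crossprod(WA, y)))
    phi <- c(phi_head, (fx - base) - sum(phi_head))
    vals[i, ] <- phi
  }
  list(values = vals, base_value = base)
}

#' Adaptive IQR outlier filtering of attributions
#'
#' Per gene, extreme attribution values are zeroed using dynamic bounds
#' `[Q1 - k*IQR, Q3 + k*IQR]`. The multiplier k is searched over
#' `k_grid` in descending order (so the least aggressive acceptable
#' filter wins) and the first k whose zeroed fraction falls inside
#' `ratio_band` is accepted. If no k lands in the band, a percentile
#' fallback zeroes the values outside the empirical 1st/99th
#' percentiles. Genes with zero IQR are left untouched (`method =
#' "none"`).
#'
#' Filtered values drive global interpretation; unfiltered values are
#' kept alongside for local explanations.
#'
#' @param attr An `attribution_set`.
#' @param ratio_band Acceptable zeroed-fraction interval for the IQR
#'   branch.
#' @param k_grid Descending IQR multipliers to try.
#' @param fallback_percentiles Lower/upper percentile bounds for the
#'   fallback (in percent).
#' @return The `attribution_set` with `filtered_values` and
#'   `filter_report` (data.frame gene/method/iqr_multiplier/
#'   fraction_zeroed/lower/upper) populated.
#' @export
filter_outliers <- function(attr, ratio_band = c(0.05, 0.10),
                            k_grid = seq(3, 0.5, by = -0.25),
                            fallback_percentiles = c(1, 99)) {
  stopifnot(inherits(attr, "attribution_set"))
  V <- attr$values
  if (nrow(V) == 0) stop("attribution set has no samples")
  if (any(!is.finite(V))) stop("attributions must be finite")
  filt <- V
  rep_rows <- vector("list", ncol(V))
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    method <- "none"; kk <- NA_real_; frac <- 0
    lo <- -Inf; hi <- Inf
    if (iqr > 0) {
      for (k in k_grid) {
        b_lo <- q[1] - k * iqr; b_hi <- q[2] + k * iqr
        fr <- mean(v < b_lo | v > b_hi)
        if (fr >= ratio_band[1] && fr <= ratio_band[2]) {
          method <- "iqr"; kk <- k; frac <- fr; lo <- b_lo; hi <- b_hi
          break
        }
      }
      if (method == "none") {
        pb <- stats::quantile(v, fallback_percentiles / 100, names = FALSE)
        fr <- mean(v < pb[1] | v > pb[2])
        if (fr > 0) {
          method <- "percentile_fallback"; frac <- fr
          lo <- pb[1]; hi <- pb[2]
        }
      }
    }
    if (method != "none") filt[v < lo | v > hi, j] <- 0
    rep_rows[[j]] <- data.frame(gene = colnames(V)[j], method = method,
                                iqr_multiplier = kk, fraction_zeroed = frac,
                                lower = lo, upper = hi)
  }
  attr$filtered_values <- filt
  attr$filter_report <- do.call(rbind, rep_rows)
  attr
}

#' Global gene importance from attributions
#'
#' Per-gene mean absolute attribution (filtered by default, as the
#' global view), returned in descending order with deterministic
#' tie-breaks by gene id.
#'
#' @param attr An `attribution_set` (filtered if `use_filtered`).
#' @param use_filtered Use the outlier-filtered matrix (requires
#'   [filter_outliers()] to have run).
#' @return Named numeric vector of importances, descending.
#' @export
global_importance <- function(attr, use_filtered = TRUE) {
  stopifnot(inherits(attr, "attribution_set"))
  V <- if (use_filtered) {
    if (is.null(attr$filtered_values))
      stop("no filtered values; run filter_outliers() first")
    attr$filtered_values
  } else attr$values
  imp <- colMeans(abs(V))
  imp[order(-imp, names(imp))]
}

#' Dependence-plot data for one gene
#'
#' Per-sample table of the gene's expression, its attribution, and the
#' expression of an interaction gene. With `interaction = "auto"`, the
#' candidate whose expression most strongly modulates the target's
#' attribution-expression relationship is chosen: samples are split at
#' the candidate's median and the absolute difference of the two
#' within-half regression slopes (attribution on expression) is
#' maximized.
#'
#' @param attr An `attribution_set`.
#' @param expr Expression matrix covering the explained samples
#'   (unscaled values for plotting).
#' @param gene Target gene id.
#' @param interaction A gene id, or `"auto"`.
#' @param drop_filtered Drop rows whose target attribution was zeroed
#'   by the outlier filter.
#' @return data.frame with sample_id, expression, attribution,
#'   interaction_gene, interaction_expression.
#' @export
dependence_data <- function(attr, expr, gene, interaction = "auto",
                            drop_filtered = FALSE) {
  stopifnot(inherits(attr, "attribution_set"))
  if (!gene %in% colnames(attr$values))
    stop("unknown gene: ", gene)
  ids <- rownames(attr$values)
  E <- expr[ids, colnames(attr$values), drop = FALSE]
  a <- attr$values[, gene]
  if (identical(interaction, "auto")) {
    interaction <- auto_interaction(E, a, gene)
  } else if (!interaction %in% colnames(E)) {
    stop("unknown interaction gene: ", interaction)
  }
  out <- data.frame(sample_id = ids,
                    expression = E[, gene],
                    attribution = a,
                    interaction_gene = interaction,
                    interaction_expression = E[, interaction],
                    row.names = NULL)
  if (drop_filtered) {
    if (is.null(attr$filtered_values))
      stop("no filtered values; run filter_outliers() first")
    keep <- attr$filtered_values[, gene] == attr$values[, gene] |
      attr$filtered_values[, gene] != 0
    out <- out[keep, , drop = FALSE]
  }
  out
}

# slope-contrast heuristic for the strongest interacting gene
auto_interaction <- function(E, a, gene) {
  x <- E[, gene]
  cands <- setdiff(colnames(E), gene)
  sc <- vapply(cands, function(g) {
    split_at <- stats::median(E[, g])
    lo <- E[, g] <= split_at
    if (sum(lo) < 3 || sum(!lo) < 3) return(0)
    s1 <- slope(x[lo], a[lo]); s2 <- slope(x[!lo], a[!lo])
    if (!is.finite(s1) || !is.finite(s2)) return(0)
    abs(s1 - s2)
  }, numeric(1))
  cands[which.max(sc)]
}

slope <- function(x, y) {
  vx <- stats::var(x)
  if (vx == 0) return(NA_real_)
  stats::cov(x, y) / vx
}

#' Local explanation for one sample
#'
#' Top genes by absolute unfiltered attribution for a single sample,
#' signed and in descending order of magnitude (the data behind a
#' force-style plot).
#'
#' @param attr An `attribution_set`.
#' @param sample_id Row id of the sample.
#' @param top_k Number of genes returned (capped at the gene count).
#' @return data.frame with gene, attribution; attribute `base_value`.
#' @export
local_explanation <- function(attr, sample_id, top_k = 10L) {
  stopifnot(inherits(attr, "attribution_set"))
  if (!sample_id %in% rownames(attr$values))
    stop("unknown sample: ", sample_id)
  v <- attr$values[sample_id, ]
  ord <- order(-abs(v), names(v))
  k <- min(top_k, length(v))
  out <- data.frame(gene = names(v)[ord[seq_len(k)]],
                    attribution = as.numeric(v[ord[seq_len(k)]]),
                    row.names = NULL)
  attr(out, "base_value") <- attr$base_value
  out
}
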