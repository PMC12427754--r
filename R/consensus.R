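#' AUC-weighted cross-model consensus gene ranking
#'
#' Aggregates per-model global importances (mean absolute attribution
#' per gene, typically from [global_importance()]) into one ranking:
#' each model's importance vector is min-max scaled to [0, 1] across
#' genes, multiplied by the model's test-set AUC, and summed across the
#' non-excluded models. The decision-tree family is excluded by default
#' for its unstable attribution behaviour, but excluded models remain
#' available to [agreement_matrix()] for comparison.
#'
#' @param importances Named list (model -> named importance vector);
#'   gene sets are unified, missing genes scored 0.
#' @param aucs Named numeric vector of test AUC weights (same names).
#' @param exclude Models left out of the aggregation (default `"DT"`).
#' @param top_k Number of top genes extracted (default 15).
#' @return An object of class `consensus_ranking`: `per_model_scaled`
#'   (matrix models x genes), `model_weights`, `scores` (named,
#'   descending), `excluded_models`, `top_k`.
#' @export
weighted_consensus <- function(importances, aucs, exclude = "DT",
                               top_k = 15L) {
  models <- names(importances)
  use <- setdiff(models, exclude)
  if (!length(use)) stop("all models excluded from the consensus")
  genes <- sort(unique(unlist(lapply(importances, names))))
  mat <- t(vapply(models, function(m) {
    v <- importances[[m]][genes]
    v[is.na(v)] <- 0
    names(v) <- genes
    v
  }, numeric(length(genes))))
  scaled <- t(apply(mat, 1, minmax_scale))
  dimnames(scaled) <- list(models, genes)
  w <- aucs[use]
  scores <- as.numeric(w %*% scaled[use, , drop = FALSE])
  names(scores) <- genes
  scores <- scores[order(-scores, genes)]
  structure(list(per_model_scaled = scaled,
                 model_weights = aucs[models],
                 scores = scores,
                 excluded_models = intersect(models, exclude),
                 top_k = names(scores)[seq_len(min(top_k, length(scores)))]),
            class = "consensus_ranking")
}

minmax_scale <- function(v) {
  rng <- range(v)
  if (rng[2] == rng[1]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("consensus ranking over",
      nrow(x$per_model_scaled) - length(x$excluded_models), "models")
  if (length(x$excluded_models))
    cat(" (excluded:", paste(x$excluded_models, collapse = ", "), ")")
  cat("\n  top genes:", paste(utils::head(x$top_k, 10), collapse = ", "),
      "\n")
  invisible(x)
}

#' Pairwise Spearman agreement of model gene rankings
#'
#' For each model pair, genes with nonzero importance in both models
#' are identified and the Spearman rank correlation of the two
#' importance vectors is computed over those shared genes (average
#' ranks for ties). Pairs with fewer than 3 shared genes are flagged
#' `NA`.
#'
#' @param importances Named list (model -> named importance vector).
#' @return An object of class `agreement_matrix`: `rho` (symmetric
#'   matrix, unit diagonal), `shared` (pairwise shared-gene counts).
#' @export
agreement_matrix <- function(importances) {
  models <- names(importances)
  if (length(models) < 2L) stop("need at least two models")
  k <- length(models)
  rho <- matrix(NA_real_, k, k, dimnames = list(models, models))
  shared <- matrix(0L, k, k, dimnames = list(models, models))
  diag(rho) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- importances[[i]]; b <- importances[[j]]
    common <- intersect(names(a)[a != 0], names(b)[b != 0])
    shared[i, j] <- shared[j, i] <- length(common)
    if (length(common) >= 3L) {
      r <- stats::cor(a[common], b[common], method = "spearman")
      rho[i, j] <- rho[j, i] <- r
    }
  }
  diag(shared) <- vapply(importances, function(v) sum(v != 0), integer(1))
  structure(list(rho = rho, shared = shared), class = "agreement_matrix")
}

#' Top-k overlap between two consensus rankings
#'
#' Number of genes shared by the top-k of two rankings (e.g. primary
#' vs external validation cohort). If `k` exceeds a ranking's length,
#' the full ranking is used with a warning.
#'
#' @param ranking_a,ranking_b `consensus_ranking` objects (or plain
#'   character vectors of ranked genes).
#' @param k Depth of the comparison (default 15).
#' @return Integer overlap count.
#' @export
topk_overlap <- function(ranking_a, ranking_b, k = 15L) {
  ga <- ranked_genes(ranking_a)
  gb <- ranked_genes(ranking_b)
  if (!length(ga) || !length(gb)) stop("empty ranking")
  if (k > length(ga) || k > length(gb))
    warning("k exceeds a ranking's length; using the full ranking")
  length(intersect(utils::head(ga, k), utils::head(gb, k)))
}

ranked_genes <- function(r) {
  if (inherits(r, "consensus_ranking")) names(r$scores) else as.character(r)
}
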