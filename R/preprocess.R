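#' Exclude flagged (symptomatic) control samples
#'
#' Removes samples carrying the exclusion flag as well as samples with a
#' missing class label, keeping the original row order. In the cohorts
#' this package targets, the flag marks controls with chronic
#' inflammation, systemic disease or cancer-like conditions whose
#' confounding molecular activity would blur the cancer/control
#' contrast.
#'
#' @param metadata Sample metadata data.frame with at least the columns
#'   `flagged` (0/1 or logical) and `label`.
#' @return The filtered metadata (same columns, original order).
#' @export
exclude_flagged <- function(metadata) {
  if (!"flagged" %in% names(metadata))
    stop("metadata lacks the required 'flagged' column")
  keep <- !as.logical(metadata$flagged) & !is.na(metadata$label) &
    metadata$label != ""
  metadata[keep, , drop = FALSE]
}

#' ANOVA screening of genes with FDR control and a gene cap
#'
#' Stage one of the three-stage feature selection: a label-stratified
#' random `discovery_fraction` of the samples (the "discovery subset")
#' is drawn, a one-way ANOVA F test across the class groups is computed
#' per gene on that subset, p values are adjusted by Benjamini-Hochberg,
#' and genes with adjusted q below `fdr` are retained. If more than
#' `cap` genes pass, the `cap` genes with the smallest q are kept (ties
#' broken towards larger F). Constant genes, for which F is undefined,
#' are assigned q = 1 and never pass.
#'
#' The discovery subset remains part of the training pool downstream;
#' its sample ids are recorded in the report so leakage checks can
#' reason about it explicitly.
#'
#' @param expr Samples x genes numeric matrix with sample ids as row
#'   names.
#' @param metadata Metadata aligned to `expr` (matched on `sample_id`).
#' @param discovery_fraction Fraction of samples used for screening.
#' @param fdr Benjamini-Hochberg threshold on adjusted q values.
#' @param cap Maximum number of genes retained.
#' @param seed Seed for the stratified discovery draw.
#' @param group_col Metadata column defining the ANOVA groups.
#' @return A `feature_selection_report` list: `discovery_sample_ids`,
#'   `anova_pass` (data.frame gene/F/q for passing genes, ascending q),
#'   `capped` (character, priority order), `retained` (initially equal
#'   to `capped`; updated by [correlation_prune()]), `dropped_pairs`.
#' @export
anova_select <- function(expr, metadata, discovery_fraction = 0.33,
                         fdr = 0.001, cap = 300L, seed = 1L,
                         group_col = "label") {
  stopifnot(nrow(expr) == nrow(metadata))
  metadata <- metadata[match(rownames(expr), metadata$sample_id), ]
  set.seed(seed)
  idx <- stratified_indices(metadata[[group_col]], discovery_fraction)
  disc_ids <- rownames(expr)[idx]
  groups <- factor(metadata[[group_col]][idx])
  if (nlevels(droplevels(groups)) < 2L)
    stop("discovery subset contains a single group; cannot run ANOVA")
  ft <- anova_f_vectorized(expr[idx, , drop = FALSE], droplevels(groups))
  q <- stats::p.adjust(ft$p, method = "BH")
  q[!is.finite(ft$F)] <- 1            # constant genes: F undefined
  pass <- which(q < fdr)
  # priority: ascending q, ties broken by larger F, then gene id
  ordp <- pass[order(q[pass], -ft$F[pass], colnames(expr)[pass])]
  capped <- utils::head(ordp, cap)
  report <- list(
    discovery_sample_ids = disc_ids,
    anova_table = data.frame(gene = colnames(expr), F = ft$F, q = q,
                             row.names = NULL),
    anova_pass = data.frame(gene = colnames(expr)[ordp], F = ft$F[ordp],
                            q = q[ordp], row.names = NULL),
    capped = colnames(expr)[capped],
    retained = colnames(expr)[capped],
    dropped_pairs = data.frame(kept = character(0), dropped = character(0),
                               r = numeric(0))
  )
  class(report) <- "feature_selection_report"
  report
}

# per-gene one-way ANOVA F statistics, fully vectorized
anova_f_vectorized <- function(X, groups) {
  n <- nrow(X); k <- nlevels(groups)
  gm <- colMeans(X)
  counts <- tabulate(groups, k)
  group_sums <- rowsum(X, groups, reorder = TRUE)
  group_means <- group_sums / counts                    # k x g
  dev <- group_means - matrix(gm, nrow = k, ncol = ncol(X), byrow = TRUE)
  ss_between <- colSums(counts * dev^2)
  ss_total <- colSums(X^2) - n * gm^2
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- k - 1L; df2 <- n - k
  Fv <- (ss_between / df1) / (ss_within / df2)
  Fv[ss_within <= 1e-12 * pmax(ss_total, 1)] <- NA_real_  # degenerate genes
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  p[is.na(p)] <- 1
  list(F = Fv, p = p)
}

# stratified sample of round(fraction * n_g) indices per stratum
stratified_indices <- function(strata, fraction) {
  unlist(lapply(split(seq_along(strata), strata), function(ix) {
    sample(ix, max(1L, round(fraction * length(ix))))
  }), use.names = FALSE)
}

#' Greedy correlation pruning of a prioritized gene list
#'
#' Stage two of the feature selection: genes are scanned in priority
#' order; a gene is dropped iff its absolute Pearson correlation with
#' any already-retained gene exceeds `r_threshold`. Dropped pairs are
#' recorded as (kept gene, dropped gene, r). Zero-variance genes have
#' undefined correlations; these are treated as r = 0 (never pruned for
#' correlation) and listed in the `zero_variance` attribute.
#'
#' @param expr Samples x genes matrix covering at least `genes`.
#' @param genes Character vector in selection-priority order
#'   (typically ascending ANOVA q).
#' @param r_threshold Absolute Pearson correlation above which the
#'   later gene of a pair is dropped.
#' @return List with `retained` (character), `dropped_pairs`
#'   (data.frame kept/dropped/r) and attribute-style `zero_variance`.
#' @export
correlation_prune <- function(expr, genes, r_threshold = 0.8) {
  stopifnot(all(genes %in% colnames(expr)))
  X <- expr[, genes, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  zv <- genes[sds == 0]
  cm <- suppressWarnings(stats::cor(X))
  cm[!is.finite(cm)] <- 0             # zero-variance convention
  retained <- character(0)
  kept_col <- integer(0)
  dropped <- data.frame(kept = character(0), dropped = character(0),
                        r = numeric(0))
  for (j in seq_along(genes)) {
    if (length(kept_col)) {
      rs <- cm[kept_col, j]
      hit <- which(abs(rs) > r_threshold)
      if (length(hit)) {
        h <- hit[1L]
        dropped <- rbind(dropped, data.frame(
          kept = genes[kept_col[h]], dropped = genes[j], r = rs[h]))
        next
      }
    }
    retained <- c(retained, genes[j])
    kept_col <- c(kept_col, j)
  }
  list(retained = retained, dropped_pairs = dropped, zero_variance = zv)
}

#' Three-stage feature selection in one call
#'
#' Runs [anova_select()] followed by [correlation_prune()] (priority =
#' ascending BH q) and returns the combined report.
#'
#' @inheritParams anova_select
#' @inheritParams correlation_prune
#' @return A `feature_selection_report` with `retained` set to the
#'   post-pruning gene list and `dropped_pairs` filled in.
#' @export
select_features <- function(expr, metadata, discovery_fraction = 0.33,
                            fdr = 0.001, cap = 300L, r_threshold = 0.8,
                            seed = 1L) {
  rep <- anova_select(expr, metadata, discovery_fraction, fdr, cap, seed)
  pr <- correlation_prune(expr[rep$discovery_sample_ids, , drop = FALSE],
                          rep$capped, r_threshold)
  rep$retained <- pr$retained
  rep$dropped_pairs <- pr$dropped_pairs
  rep
}

#' Fit / apply fold-local z-score scaling
#'
#' `fit_scaler()` records per-gene mean and standard deviation from the
#' training rows of the current fold; `apply_scaler()` transforms any
#' matrix with those frozen statistics, so held-out rows never
#' influence the scaling. Genes with zero training variance map to 0.
#'
#' @param expr_train Training-rows expression matrix.
#' @return `fit_scaler()`: an object of class `scaler_params`;
#'   `apply_scaler()`: the scaled matrix (same dimnames).
#' @export
fit_scaler <- function(expr_train) {
  structure(list(mean = colMeans(expr_train),
                 sd = apply(expr_train, 2, stats::sd),
                 genes = colnames(expr_train)),
            class = "scaler_params")
}

#' @rdname fit_scaler
#' @param params A fitted `scaler_params`.
#' @param expr Matrix to transform (columns must cover `params$genes`).
#' @export
apply_scaler <- function(params, expr) {
  if (!inherits(params, "scaler_params"))
    stop("apply_scaler() requires params fitted by fit_scaler()")
  expr <- expr[, params$genes, drop = FALSE]
  sd <- params$sd
  sd[sd == 0] <- Inf                  # zero-variance genes -> 0
  scaled <- sweep(sweep(expr, 2, params$mean, "-"), 2, sd, "/")
  scaled
}

#' Harmonize an external cohort to the training feature space
#'
#' Removes samples whose ids overlap the primary cohort, restricts the
#' gene set to the intersection with the training genes (kept in
#' training order), and applies the training-fitted scaler, so the
#' external matrix is expressed in exactly the coordinates the models
#' were trained in.
#'
#' @param train_genes Character vector of training feature genes.
#' @param external A cohort-shaped list with `expression` and
#'   `metadata`.
#' @param scaler `scaler_params` fitted on the training cohort.
#' @param overlap_ids Sample ids shared with the primary cohort; these
#'   rows are dropped.
#' @return List with `expression` (scaled, deduplicated, intersected),
#'   `metadata` (rows aligned) and `missing_genes` (training genes
#'   absent from the external cohort).
#' @export
harmonize_external <- function(train_genes, external, scaler,
                               overlap_ids = character(0)) {
  expr <- external$expression
  meta <- external$metadata
  common <- intersect(train_genes, colnames(expr))
  if (!length(common))
    stop("no genes shared between training and external cohorts")
  missing <- setdiff(train_genes, common)
  keep <- !(rownames(expr) %in% overlap_ids)
  expr <- expr[keep, train_genes[train_genes %in% common], drop = FALSE]
  meta <- meta[match(rownames(expr), meta$sample_id), , drop = FALSE]
  sub_scaler <- structure(list(mean = scaler$mean[common],
                               sd = scaler$sd[common], genes = common),
                          class = "scaler_params")
  list(expression = apply_scaler(sub_scaler, expr), metadata = meta,
       missing_genes = missing)
}
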