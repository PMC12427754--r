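test_that("flag exclusion keeps unflagged labelled rows in order", {
  md <- data.frame(sample_id = paste0("s", 1:6),
                   label = c("cancer", "control", NA, "cancer",
                             "control", "cancer"),
                   flagged = c(0, 1, 0, 0, 0, 1))
  out <- exclude_flagged(md)
  expect_equal(out$sample_id, c("s1", "s4", "s5"))
  # idempotence
  expect_equal(exclude_flagged(out), out)
  # no flags and all labels -> identity
  md2 <- data.frame(sample_id = c("a", "b"), label = c("cancer", "control"),
                    flagged = c(0, 0))
  expect_equal(exclude_flagged(md2), md2)
  # all controls flagged -> only cancer remains
  md3 <- data.frame(sample_id = paste0("s", 1:4),
                    label = c("cancer", "control", "control", "cancer"),
                    flagged = c(0, 1, 1, 0))
  expect_true(all(exclude_flagged(md3)$label == "cancer"))
  expect_error(exclude_flagged(md3[, c("sample_id", "label")]), "flagged")
})

test_that("ANOVA F, BH q and pass/fail match a brute-force oracle on a toy", {
  # 5 genes, 12 samples, hand-checkable group structure; oracle = direct
  # formula evaluation via lm/anova per gene + manual step-up
  set.seed(4)
  n <- 12
  lab <- rep(c("cancer", "control"), each = 6)
  X <- cbind(
    g1 = c(rnorm(6, 3), rnorm(6, 0)),   # strong
    g2 = c(rnorm(6, 1), rnorm(6, 0)),   # weak
    g3 = rnorm(12),                     # null
    g4 = rep(5, 12),                    # constant -> q = 1
    g5 = c(rnorm(6, -2), rnorm(6, 2))   # strong, opposite sign
  )
  rownames(X) <- paste0("s", 1:n)
  md <- data.frame(sample_id = rownames(X), label = lab, flagged = 0)
  rep_full <- anova_select(X, md, discovery_fraction = 1, fdr = 0.05,
                           cap = 10, seed = 1)
  oracle_F <- suppressWarnings(vapply(colnames(X), function(g) {
    fit <- stats::anova(stats::lm(X[, g] ~ factor(lab)))
    fit$`F value`[1]
  }, numeric(1)))
  oracle_p <- suppressWarnings(vapply(colnames(X), function(g) {
    stats::anova(stats::lm(X[, g] ~ factor(lab)))$`Pr(>F)`[1]
  }, numeric(1)))
  oracle_p["g4"] <- 1   # constant gene convention
  oracle_q <- stats::p.adjust(oracle_p, "BH")
  tab <- rep_full$anova_table
  expect_equal(tab$F[match(c("g1", "g2", "g3", "g5"), tab$gene)],
               unname(oracle_F[c("g1", "g2", "g3", "g5")]), tolerance = 1e-10)
  expect_equal(tab$q[match(colnames(X), tab$gene)], unname(oracle_q),
               tolerance = 1e-10)
  expect_setequal(rep_full$capped, names(which(oracle_q < 0.05)))
  expect_false("g4" %in% rep_full$capped)
})

test_that("the gene cap keeps exactly `cap` genes with smallest q", {
  set.seed(6)
  n <- 200
  lab <- rep(c("cancer", "control"), each = n / 2)
  shift <- matrix(rep(c(2, 0), each = n / 2), n, 600)
  X <- matrix(rnorm(n * 600), n, 600) + shift
  colnames(X) <- sprintf("g%03d", 1:600)
  rownames(X) <- sprintf("s%03d", 1:n)
  md <- data.frame(sample_id = rownames(X), label = lab, flagged = 0)
  rep <- anova_select(X, md, discovery_fraction = 1, fdr = 0.001,
                      cap = 300, seed = 1)
  expect_gt(nrow(rep$anova_pass), 300)        # all 600 genes pass
  expect_length(rep$capped, 300)
  # capped genes have the smallest q among passers
  qs <- rep$anova_pass$q
  expect_lte(max(qs[seq_len(300)]), min(qs[-seq_len(300)]))
})

test_that("correlation pruning matches a hand-run greedy scan", {
  # 6 genes with a designed correlation pattern: g2 duplicates g1,
  # g4 = g3 + noise (r > 0.8), g5/g6 independent
  set.seed(9)
  n <- 500
  g1 <- rnorm(n); g3 <- rnorm(n)
  X <- cbind(g1 = g1, g2 = g1, g3 = g3, g4 = g3 + rnorm(n, 0, 0.3),
             g5 = rnorm(n), g6 = rnorm(n))
  rownames(X) <- paste0("s", 1:n)
  cm <- cor(X)
  # oracle: manual greedy pass over the printed correlation matrix
  expect_gt(abs(cm["g3", "g4"]), 0.8)
  out <- correlation_prune(X, colnames(X), r_threshold = 0.8)
  expect_equal(out$retained, c("g1", "g3", "g5", "g6"))
  expect_setequal(out$dropped_pairs$dropped, c("g2", "g4"))
  expect_equal(out$dropped_pairs$kept[out$dropped_pairs$dropped == "g2"],
               "g1")
  # idempotence: pruning the retained set drops nothing
  again <- correlation_prune(X, out$retained, 0.8)
  expect_equal(again$retained, out$retained)
  expect_equal(nrow(again$dropped_pairs), 0L)
})

test_that("pruning is monotone in the threshold and spares zero-variance genes", {
  set.seed(10)
  X <- matrix(rnorm(300 * 8), 300, 8)
  X[, 8] <- 3                                  # zero variance
  X[, 2] <- X[, 1] * 0.95 + rnorm(300, 0, 0.2)
  colnames(X) <- paste0("g", 1:8)
  n_kept <- vapply(c(0.9, 0.7, 0.5, 0.3), function(thr)
    length(correlation_prune(X, colnames(X), thr)$retained), numeric(1))
  expect_true(all(diff(n_kept) <= 0))
  out <- correlation_prune(X, colnames(X), 0.5)
  expect_true("g8" %in% out$retained)          # r treated as 0
  expect_true("g8" %in% out$zero_variance)
})

test_that("fold scaling uses frozen training statistics only", {
  set.seed(2)
  tr <- matrix(rnorm(50 * 4, mean = 5, sd = 2), 50, 4,
               dimnames = list(NULL, paste0("g", 1:4)))
  te <- matrix(rnorm(4 * 4, mean = 9, sd = 1), 4, 4,
               dimnames = list(NULL, paste0("g", 1:4)))
  sc <- fit_scaler(tr)
  z_tr <- apply_scaler(sc, tr)
  expect_equal(unname(colMeans(z_tr)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(z_tr, 2, sd)), rep(1, 4), tolerance = 1e-9)
  # held-out rows scaled with training stats != self-scaled values
  z_te_frozen <- apply_scaler(sc, te)
  z_te_self <- apply_scaler(fit_scaler(te), te)
  expect_gt(max(abs(z_te_frozen - z_te_self)), 0.1)
  # direct recomputation oracle on the first test row
  expect_equal(z_te_frozen[1, ], (te[1, ] - sc$mean) / sc$sd)
  # constant gene maps to zero
  tr2 <- cbind(tr, g5 = rep(7, 50))
  z2 <- apply_scaler(fit_scaler(tr2), tr2)
  expect_true(all(z2[, "g5"] == 0))
  expect_error(apply_scaler(list(mean = 0), tr), "fit_scaler")
})

test_that("external harmonization dedups, intersects and scales", {
  base <- small_cohort(n_cancer = 60, n_control = 40, n_flagged = 0,
                       n_genes = 40, n_informative = 4, seed = 17)
  ext <- generate_external_cohort(base, n_samples = 285, n_overlap = 30,
                                  gene_subset_fraction = 0.5, seed = 18)
  train_genes <- colnames(base$expression)
  scaler <- fit_scaler(base$expression)
  overlap <- intersect(rownames(ext$expression), rownames(base$expression))
  out <- harmonize_external(train_genes, ext, scaler, overlap)
  expect_equal(nrow(out$expression), 255)
  # oracle: explicit set intersection
  expect_equal(ncol(out$expression),
               length(intersect(train_genes, colnames(ext$expression))))
  expect_setequal(out$missing_genes,
                  setdiff(train_genes, colnames(ext$expression)))
  # no overlap + identical genes -> scaling only
  ext2 <- generate_external_cohort(base, 20, 0, 1.0, seed = 19)
  out2 <- harmonize_external(train_genes, ext2, scaler, character(0))
  expect_equal(out2$expression,
               apply_scaler(scaler, ext2$expression))
  bad <- list(expression = matrix(0, 2, 2,
                                  dimnames = list(c("a", "b"), c("zz1", "zz2"))),
              metadata = data.frame(sample_id = c("a", "b")))
  expect_error(harmonize_external(train_genes, bad, scaler), "shared")
})

test_that("discovery subset is stratified and leak-checkable", {
  co <- small_cohort(seed = 23)
  meta <- exclude_flagged(co$metadata)
  expr <- co$expression[meta$sample_id, ]
  rep <- anova_select(expr, meta, discovery_fraction = 0.33, fdr = 0.05,
                      cap = 50, seed = 5)
  ids <- rep$discovery_sample_ids
  expect_equal(length(ids), length(unique(ids)))
  expect_true(all(ids %in% meta$sample_id))
  # stratification: both labels near their 33% share
  sub_lab <- meta$label[match(ids, meta$sample_id)]
  for (lv in c("cancer", "control")) {
    expect_equal(sum(sub_lab == lv), round(0.33 * sum(meta$label == lv)),
                 tolerance = 1)
  }
  # determinism
  rep2 <- anova_select(expr, meta, 0.33, 0.05, 50, seed = 5)
  expect_identical(rep$discovery_sample_ids, rep2$discovery_sample_ids)
  expect_identical(rep$capped, rep2$capped)
})
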