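# Small in-code fixtures shared across test files.

small_cohort <- function(n_cancer = 120, n_control = 60, n_flagged = 20,
                         n_genes = 120, n_informative = 6,
                         effect_size = 1.5, seed = 11, ...) {
  generate_cohort(cohort_config(
    n_cancer = n_cancer, n_control = n_control,
    n_flagged_controls = n_flagged, n_genes = n_genes,
    n_informative = n_informative, effect_size = effect_size,
    seed = seed, ...))
}

# metadata table with hand-set covariates for split tests
toy_metadata <- function(n = 20, seed = 3) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("T%03d", seq_len(n)),
    label = rep(c("cancer", "control"), length.out = n),
    cancer_type = rep(c("typeA", "typeB"), each = n / 2),
    stage = "I",
    age = round(rnorm(n, 60, 10), 1),
    sex = rep(c("F", "M"), length.out = n),
    institution = rep(c("inst1", "inst2"), length.out = n),
    flagged = 0L,
    stringsAsFactors = FALSE
  )
}

# a fitted LR pipeline on a small strong-signal cohort, reused by
# attribution tests (cheap to fit)
fit_small_model <- function(family = "LR", cohort = NULL, seed = 21,
                            n_search_iters = 2, cv_folds = 3) {
  if (is.null(cohort)) cohort <- small_cohort(seed = seed)
  meta <- exclude_flagged(cohort$metadata)
  expr <- cohort$expression[meta$sample_id, , drop = FALSE]
  genes <- utils::head(colnames(expr), 12)
  cfg <- model_config(family, n_search_iters = n_search_iters,
                      cv_folds = cv_folds, seed = seed)
  fit <- tune_and_fit(build_model(cfg), expr[, genes], meta$label)
  list(model = fit, expr = expr[, genes], meta = meta, genes = genes)
}
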