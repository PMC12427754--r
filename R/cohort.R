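#' Configuration for a synthetic platelet-RNA cohort
#'
#' Describes a synthetic cohort that mimics the structure of a curated
#' platelet RNA-seq case/control study: imbalanced cancer vs control
#' classes, a block of symptomatic ("flagged") controls slated for
#' downstream exclusion, cancer-type strata with stage labels, a
#' multi-centre institution covariate, age/sex demographics, and a
#' planted set of informative genes with a configurable standardized
#' effect size. Expression is generated on a normalized (log-like)
#' scale, with optional correlated gene blocks driven by shared latent
#' factors.
#'
#' @param n_cancer Number of cancer samples.
#' @param n_control Number of retained (asymptomatic) control samples.
#' @param n_flagged_controls Number of additional symptomatic control
#'   samples carrying an exclusion flag. These receive a mild
#'   perturbation on a random gene subset to emulate confounding
#'   molecular activity.
#' @param n_genes Total number of genes.
#' @param n_informative Number of planted informative genes.
#' @param effect_size Standardized class-conditional mean shift
#'   (Cohen's d) per informative gene.
#' @param block_size Genes per correlated block (1 = independent genes).
#' @param block_rho Target pairwise correlation within a block, in [0, 1).
#' @param n_types Number of cancer-type strata.
#' @param stage_probs Probability vector over stages I, II, III, IV,
#'   unknown (cancer samples only). Must sum to 1.
#' @param n_institutions Number of contributing institutions.
#' @param age_mean,age_sd Age distribution (years).
#' @param sex_prob Probability of sex "F".
#' @param flagged_effect Perturbation magnitude for flagged controls, in
#'   standardized units; defaults to half the planted effect size.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_cancer = 1628L,
                          n_control = 390L,
                          n_flagged_controls = 333L,
                          n_genes = 2000L,
                          n_informative = 20L,
                          effect_size = 1.5,
                          block_size = 10L,
                          block_rho = 0.3,
                          n_types = 18L,
                          stage_probs = c(I = 0.1, II = 0.2, III = 0.25,
                                          IV = 0.3, unknown = 0.15),
                          n_institutions = 4L,
                          age_mean = 60,
                          age_sd = 12,
                          sex_prob = 0.5,
                          flagged_effect = NULL,
                          seed = 1L) {
  cfg <- list(
    n_cancer = as.integer(n_cancer),
    n_control = as.integer(n_control),
    n_flagged_controls = as.integer(n_flagged_controls),
    n_genes = as.integer(n_genes),
    n_informative = as.integer(n_informative),
    effect_size = as.numeric(effect_size),
    block_size = as.integer(block_size),
    block_rho = as.numeric(block_rho),
    n_types = as.integer(n_types),
    stage_probs = stage_probs,
    n_institutions = as.integer(n_institutions),
    age_mean = as.numeric(age_mean),
    age_sd = as.numeric(age_sd),
    sex_prob = as.numeric(sex_prob),
    flagged_effect = if (is.null(flagged_effect)) 0.5 * effect_size
                     else as.numeric(flagged_effect),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  counts <- c("n_cancer", "n_control", "n_flagged_controls", "n_genes",
              "n_informative", "block_size", "n_types", "n_institutions")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("invalid cohort config: field '", f, "' must be a non-negative count")
  }
  if (cfg$n_informative > cfg$n_genes)
    stop("invalid cohort config: field 'n_informative' exceeds 'n_genes'")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1)
    stop("invalid cohort config: field 'block_rho' must lie in [0, 1)")
  if (abs(sum(cfg$stage_probs) - 1) > 1e-9)
    stop("invalid cohort config: field 'stage_probs' must sum to 1")
  if (length(cfg$stage_probs) != 5L)
    stop("invalid cohort config: field 'stage_probs' needs 5 entries (I-IV, unknown)")
  if (cfg$sex_prob < 0 || cfg$sex_prob > 1)
    stop("invalid cohort config: field 'sex_prob' must lie in [0, 1]")
  if (cfg$block_size < 1L)
    stop("invalid cohort config: field 'block_size' must be >= 1")
  invisible(cfg)
}

gene_ids <- function(n) sprintf("GENE%04d", seq_len(n))
sample_ids <- function(n, prefix = "S") sprintf("%s%05d", prefix, seq_len(n))

#' Generate a synthetic platelet-RNA cohort with known ground truth
#'
#' Draws a samples-by-genes expression matrix on a normalized scale
#' together with aligned sample metadata. Genes are grouped in blocks
#' of `block_size`; within a block, a shared standard-normal latent
#' factor induces pairwise correlation `block_rho` while keeping unit
#' marginal variance. A random subset of `n_informative` genes receives
#' a class-conditional mean shift of `effect_size` standard deviations
#' in cancer samples. Flagged (symptomatic) controls additionally
#' receive a mild shift of `flagged_effect` on a random 10% of genes.
#'
#' Covariates (cancer type, stage, institution, age, sex) are drawn
#' independently of expression. Stage labels are assigned to cancer
#' samples only; controls carry stage `"none"` and cancer type
#' `"control"`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with
#'   `expression` (numeric matrix, samples x genes, dimnames set),
#'   `metadata` (data.frame with columns sample_id, label, cancer_type,
#'   stage, age, sex, institution, flagged), `informative_genes`
#'   (character vector of planted gene ids) and the generating `config`.
#' @examples
#' co <- generate_cohort(cohort_config(n_cancer = 60, n_control = 40,
#'                                     n_flagged_controls = 10,
#'                                     n_genes = 100, n_informative = 5,
#'                                     seed = 7))
#' dim(co$expression)
#' table(co$metadata$label, co$metadata$flagged)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_cancer + config$n_control + config$n_flagged_controls
  g <- config$n_genes
  ids <- sample_ids(n)
  genes <- gene_ids(g)

  label <- c(rep("cancer", config$n_cancer),
             rep("control", config$n_control + config$n_flagged_controls))
  flagged <- c(rep(0L, config$n_cancer + config$n_control),
               rep(1L, config$n_flagged_controls))
  # shuffle sample order so flags are not positional
  ord <- sample.int(n)
  label <- label[ord]; flagged <- flagged[ord]

  expr <- block_correlated_matrix(n, g, config$block_size, config$block_rho)
  dimnames(expr) <- list(ids, genes)

  informative <- if (config$n_informative > 0L)
    sort(sample(genes, config$n_informative)) else character(0)
  is_cancer <- label == "cancer"
  if (length(informative))
    expr[is_cancer, informative] <- expr[is_cancer, informative, drop = FALSE] +
      config$effect_size
  # symptomatic controls: mild perturbation on a random 10% of genes
  if (config$n_flagged_controls > 0L && config$flagged_effect != 0) {
    pert_genes <- sample(genes, max(1L, round(0.1 * g)))
    fl <- flagged == 1L
    expr[fl, pert_genes] <- expr[fl, pert_genes, drop = FALSE] +
      config$flagged_effect
  }

  types <- sprintf("type%02d", seq_len(max(config$n_types, 1L)))
  stages <- c("I", "II", "III", "IV", "unknown")
  metadata <- data.frame(
    sample_id = ids,
    label = label,
    cancer_type = ifelse(is_cancer,
                         sample(types, n, replace = TRUE), "control"),
    stage = ifelse(is_cancer,
                   sample(stages, n, replace = TRUE,
                          prob = config$stage_probs), "none"),
    age = round(stats::rnorm(n, config$age_mean, config$age_sd), 1),
    sex = sample(c("F", "M"), n, replace = TRUE,
                 prob = c(config$sex_prob, 1 - config$sex_prob)),
    institution = sprintf("inst%d",
                          sample.int(config$n_institutions, n, replace = TRUE)),
    flagged = flagged,
    stringsAsFactors = FALSE
  )
  structure(list(expression = expr, metadata = metadata,
                 informative_genes = informative, config = config),
            class = "synthetic_cohort")
}

# Latent-factor block construction: x = sqrt(rho) * z_block + sqrt(1-rho) * e
# gives unit variance and pairwise within-block correlation exactly rho in
# expectation.
block_correlated_matrix <- function(n, g, block_size, rho) {
  expr <- matrix(stats::rnorm(n * g), n, g)
  if (rho > 0 && block_size > 1L) {
    n_blocks <- ceiling(g / block_size)
    z <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(g)]
    expr <- sqrt(rho) * z[, block_of, drop = FALSE] + sqrt(1 - rho) * expr
  }
  expr
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic platelet-RNA cohort:",
      nrow(x$expression), "samples x", ncol(x$expression), "genes\n")
  cat("  cancer:", sum(x$metadata$label == "cancer"),
      " control:", sum(x$metadata$label == "control"),
      " flagged:", sum(x$metadata$flagged == 1L), "\n")
  cat("  planted informative genes:", length(x$informative_genes), "\n")
  invisible(x)
}

#' Generate an external validation cohort linked to a primary cohort
#'
#' Draws a fresh cohort from the same generative model as `base` but on
#' a (possibly) reduced random gene subset, and then replaces
#' `n_overlap` of its samples with verbatim copies of randomly chosen
#' `base` samples (ids and metadata carried over), emulating a public
#' validation dataset that shares some individuals with the primary
#' accession. Informative genes that survive the gene subsetting keep
#' their class-conditional shift, so the planted signal is preserved
#' across cohorts.
#'
#' @param base A `synthetic_cohort` from [generate_cohort()].
#' @param n_samples Number of samples in the external cohort.
#' @param n_overlap Number of samples copied verbatim from `base`
#'   (shared sample ids).
#' @param gene_subset_fraction Fraction of `base` genes retained
#'   (random subset; 1 keeps the identical gene set).
#' @param seed Integer seed.
#' @return A `synthetic_cohort` whose `informative_genes` are the
#'   planted genes of `base` that survive the gene subset.
#' @export
generate_external_cohort <- function(base, n_samples, n_overlap,
                                     gene_subset_fraction = 1.0,
                                     seed = 1L) {
  stopifnot(inherits(base, "synthetic_cohort"))
  n_samples <- as.integer(n_samples); n_overlap <- as.integer(n_overlap)
  if (n_overlap > n_samples)
    stop("n_overlap exceeds n_samples")
  if (n_overlap > nrow(base$expression))
    stop("n_overlap exceeds the base cohort size")
  if (gene_subset_fraction <= 0 || gene_subset_fraction > 1)
    stop("gene_subset_fraction must lie in (0, 1]")

  set.seed(seed)
  base_genes <- colnames(base$expression)
  keep_g <- if (gene_subset_fraction < 1) {
    sort(sample(base_genes, round(gene_subset_fraction * length(base_genes))))
  } else base_genes

  # fresh samples from the same generative model, no flagged block
  cfg <- base$config
  n_new <- n_samples - n_overlap
  frac_cancer <- cfg$n_cancer / (cfg$n_cancer + cfg$n_control)
  new_cfg <- cohort_config(
    n_cancer = round(frac_cancer * n_new),
    n_control = n_new - round(frac_cancer * n_new),
    n_flagged_controls = 0L,
    n_genes = cfg$n_genes, n_informative = 0L,
    effect_size = cfg$effect_size, block_size = cfg$block_size,
    block_rho = cfg$block_rho, n_types = cfg$n_types,
    stage_probs = cfg$stage_probs, n_institutions = cfg$n_institutions,
    age_mean = cfg$age_mean, age_sd = cfg$age_sd, sex_prob = cfg$sex_prob,
    seed = sample.int(.Machine$integer.max, 1L)
  )
  fresh <- generate_cohort(new_cfg)
  expr <- fresh$expression
  meta <- fresh$metadata
  # re-plant the base cohort's informative genes in the fresh samples
  informative <- intersect(base$informative_genes, colnames(expr))
  if (length(informative)) {
    is_ca <- meta$label == "cancer"
    expr[is_ca, informative] <- expr[is_ca, informative, drop = FALSE] +
      cfg$effect_size
  }
  meta$sample_id <- sample_ids(n_new, prefix = "E")
  rownames(expr) <- meta$sample_id

  if (n_overlap > 0L) {
    take <- sample(rownames(base$expression), n_overlap)
    expr <- rbind(base$expression[take, , drop = FALSE], expr)
    meta <- rbind(base$metadata[match(take, base$metadata$sample_id), ], meta)
    rownames(meta) <- NULL
  }
  expr <- expr[, keep_g, drop = FALSE]
  structure(list(expression = expr, metadata = meta,
                 informative_genes = intersect(base$informative_genes, keep_g),
                 config = base$config),
            class = "synthetic_cohort")
}

#' Write / read a cohort as plain-text CSV files
#'
#' `write_cohort()` writes `expression.csv` (first column `sample_id`,
#' one column per gene) and `metadata.csv` into `dir`; `read_cohort()`
#' reads them back into a `synthetic_cohort`-shaped list (ground-truth
#' informative genes are not serialized).
#'
#' @param cohort A `synthetic_cohort` (or any list with `expression`
#'   and `metadata` in the same shape).
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a list with `expression` and `metadata`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_df <- data.frame(sample_id = rownames(cohort$expression),
                        cohort$expression, check.names = FALSE)
  utils::write.csv(expr_df, file.path(dir, "expression.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  expr_df <- utils::read.csv(file.path(dir, "expression.csv"),
                             check.names = FALSE)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$sample_id
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  list(expression = expr, metadata = meta)
}
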