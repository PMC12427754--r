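#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a binary training set by interpolating new minority-class
#' points between each seed minority sample and one of its k nearest
#' minority neighbours (Euclidean distance, uniform interpolation
#' factor), until the minority class matches the majority count.
#' Intended to be applied inside each cross-validation training fold
#' only; synthetic rows are tagged so tests can verify they never reach
#' a validation fold.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Binary label vector (factor, character or 0/1) aligned to
#'   `X`.
#' @param k Number of nearest minority neighbours considered.
#' @return List with `X` (original rows followed by synthetic rows),
#'   `y`, `n_synthetic`, and `synthetic` (logical row mask).
#' @export
smote <- function(X, y, k = 5L) {
  y <- as.factor(y)
  stopifnot(nlevels(y) == 2L, nrow(X) == length(y))
  counts <- table(y)
  minority <- names(which.min(counts))
  need <- max(counts) - min(counts)
  if (need == 0L)
    return(list(X = X, y = y, n_synthetic = 0L,
                synthetic = rep(FALSE, nrow(X))))
  min_idx <- which(y == minority)
  Xm <- X[min_idx, , drop = FALSE]
  nm <- nrow(Xm)
  if (nm < 2L)
    stop("SMOTE needs at least 2 minority samples")
  k_eff <- min(k, nm - 1L)
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_eff)]))
  if (k_eff == 1L) nn <- matrix(nn, ncol = 1L)
  seeds <- sample.int(nm, need, replace = TRUE)
  picks <- nn[cbind(seeds, sample.int(k_eff, need, replace = TRUE))]
  gaps <- stats::runif(need)
  synth <- Xm[seeds, , drop = FALSE] +
    gaps * (Xm[picks, , drop = FALSE] - Xm[seeds, , drop = FALSE])
  rownames(synth) <- sprintf("synth%05d", seq_len(need))
  list(X = rbind(X, synth),
       y = factor(c(as.character(y), rep(minority, need)),
                  levels = levels(y)),
       n_synthetic = as.integer(need),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, need)))
}
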