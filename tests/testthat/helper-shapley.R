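# Independent brute-force Shapley oracles. Both enumerate feature
# coalitions directly; neither shares code with the package's
# attribution backends.

# Interventional Shapley values: v(S) = mean over background rows of
# f(x_S, r_{S^c}). Exact enumeration over all 2^p coalitions.
shapley_brute_force <- function(f, x, background) {
  p <- length(x)
  stopifnot(p <= 12)
  n_sub <- 2^p
  # cache v for every coalition mask
  v <- numeric(n_sub)
  for (mask in 0:(n_sub - 1)) {
    S <- as.logical(bitwAnd(mask, 2^(seq_len(p) - 1)))
    M <- background
    if (any(S))
      M[, S] <- matrix(x[S], nrow(background), sum(S), byrow = TRUE)
    v[mask + 1] <- mean(f(M))
  }
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit_j <- 2^(j - 1)
    for (mask in 0:(n_sub - 1)) {
      if (bitwAnd(mask, bit_j) > 0) next      # j must be absent from S
      s <- sum(as.logical(bitwAnd(mask, 2^(seq_len(p) - 1))))
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[j] <- phi[j] + w * (v[mask + bit_j + 1] - v[mask + 1])
    }
  }
  list(phi = phi, base_value = v[1])
}

# xgboost stores thresholds and compares features in single precision;
# replicate that, or samples lying exactly on a split boundary (e.g.
# training rows) can be routed down the wrong branch.
as_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4), "numeric",
          n = length(v), size = 4)
}

# Cover-weighted tree-path expectation of an xgboost booster: the value
# function that path-dependent TreeSHAP attributes. Masked features are
# marginalized by descending both children weighted by training covers.
xgb_tree_expectation <- function(tree_df, x, S) {
  one_tree <- function(td) {
    rec <- function(id) {
      nd <- td[td$ID == id, , drop = FALSE]
      if (nd$Feature == "Leaf") return(nd$Gain)
      j <- match(nd$Feature, names(x))
      if (S[j]) {
        child <- if (as_float32(x[j]) < as_float32(nd$Split)) nd$Yes
                 else nd$No
        return(rec(child))
      }
      cl <- td$Cover[td$ID == nd$Yes]
      cr <- td$Cover[td$ID == nd$No]
      (cl * rec(nd$Yes) + cr * rec(nd$No)) / (cl + cr)
    }
    rec(td$ID[td$Node == 0])
  }
  sum(vapply(split(tree_df, tree_df$Tree), one_tree, numeric(1)))
}

# Brute-force Shapley values of the tree-path value function above.
xgb_shapley_brute_force <- function(booster, x) {
  tree_df <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  p <- length(x)
  n_sub <- 2^p
  v <- numeric(n_sub)
  for (mask in 0:(n_sub - 1)) {
    S <- as.logical(bitwAnd(mask, 2^(seq_len(p) - 1)))
    v[mask + 1] <- xgb_tree_expectation(tree_df, x, S)
  }
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit_j <- 2^(j - 1)
    for (mask in 0:(n_sub - 1)) {
      if (bitwAnd(mask, bit_j) > 0) next
      s <- sum(as.logical(bitwAnd(mask, 2^(seq_len(p) - 1))))
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[j] <- phi[j] + w * (v[mask + bit_j + 1] - v[mask + 1])
    }
  }
  list(phi = phi, base_value = v[1])
}
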