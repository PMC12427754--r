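# Feed-forward binary classifier used for the shallow (one hidden
# layer) and deep (two hidden layer) network families: ReLU hidden
# units with inverted dropout, sigmoid output, binary cross-entropy
# loss, Adam updates, Glorot-uniform kernel initialization, and early
# stopping on validation loss with best-weight restoration.

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Train a small feed-forward neural network
#'
#' @param X Numeric feature matrix (samples x features), already scaled.
#' @param y Binary 0/1 numeric vector.
#' @param hidden Integer vector of hidden-layer sizes (length 1 for the
#'   shallow network, 2 for the deep network).
#' @param dropout Dropout rate applied after each hidden layer.
#' @param lr Adam learning rate (beta1 = 0.9, beta2 = 0.999,
#'   epsilon = 1e-7).
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience on validation loss; the best
#'   weights seen are restored.
#' @param val_fraction Fraction of rows held out (stratified) as the
#'   early-stopping validation split.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return An object of class `tep_mlp` with a [predict.tep_mlp()]
#'   method returning cancer-class probabilities.
#' @export
mlp_fit <- function(X, y, hidden = 64L, dropout = 0.1, lr = 0.001,
                    epochs = 20L, batch_size = 32L, patience = 5L,
                    val_fraction = 0.1, seed = 42L) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0, 1)))
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  sizes <- c(p, as.integer(hidden), 1L)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(l) glorot_uniform(sizes[l], sizes[l + 1]))
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))

  # stratified validation split for early stopping
  val_idx <- unlist(lapply(split(seq_len(n), y), function(ix)
    sample(ix, max(1L, round(val_fraction * length(ix))))), use.names = FALSE)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(bb) bb * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-7
  t_step <- 0
  best <- list(loss = Inf, W = W, b = b)
  wait <- 0L

  forward <- function(W, b, X, train = FALSE) {
    acts <- list(X)
    for (l in seq_len(L)) {
      z <- acts[[l]] %*% W[[l]]
      z <- sweep(z, 2, b[[l]], "+")
      if (l < L) {
        a <- pmax(z, 0)
        if (train && dropout > 0) {
          mask <- matrix(stats::rbinom(length(a), 1, 1 - dropout) /
                           (1 - dropout), nrow(a), ncol(a))
          a <- a * mask
        }
      } else a <- stats::plogis(z)
      acts[[l + 1]] <- a
    }
    acts
  }
  bce <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }

  for (epoch in seq_len(epochs)) {
    perm <- sample.int(length(tr_idx))
    for (start in seq(1, length(perm), by = batch_size)) {
      bi <- perm[start:min(start + batch_size - 1L, length(perm))]
      Xb <- Xtr[bi, , drop = FALSE]; yb <- ytr[bi]
      acts <- forward(W, b, Xb, train = TRUE)
      nb <- length(bi)
      delta <- (acts[[L + 1]] - yb) / nb       # d loss / d z_out for BCE+sigmoid
      t_step <- t_step + 1
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in L:1) {
        gW[[l]] <- crossprod(acts[[l]], delta)
        gb[[l]] <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
        }
      }
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        mh <- mW[[l]] / (1 - beta1^t_step); vh <- vW[[l]] / (1 - beta2^t_step)
        W[[l]] <- W[[l]] - lr * mh / (sqrt(vh) + eps)
        mhb <- mb[[l]] / (1 - beta1^t_step); vhb <- vb[[l]] / (1 - beta2^t_step)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
    val_loss <- bce(forward(W, b, Xval)[[L + 1]], yval)
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, W = W, b = b)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(list(W = best$W, b = best$b, sizes = sizes,
                 hidden = hidden, dropout = dropout,
                 val_loss = best$loss, genes = colnames(X)),
            class = "tep_mlp")
}

#' @rdname mlp_fit
#' @param object A fitted `tep_mlp`.
#' @param newdata Feature matrix in the training column order.
#' @param type `"prob"` for sigmoid probabilities, `"logit"` for the
#'   pre-sigmoid margin.
#' @param ... Unused.
#' @export
predict.tep_mlp <- function(object, newdata, type = c("prob", "logit"), ...) {
  type <- match.arg(type)
  a <- newdata
  L <- length(object$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else z
  }
  out <- as.numeric(a)
  if (type == "prob") stats::plogis(out) else out
}

# Gradient of the pre-sigmoid output with respect to the inputs, one
# row per sample; used by the integrated-gradients attribution backend.
mlp_input_gradient <- function(object, X) {
  L <- length(object$W)
  acts <- list(X)
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% object$W[[l]], 2, object$b[[l]], "+")
    acts[[l + 1]] <- if (l < L) pmax(z, 0) else z
  }
  delta <- matrix(1, nrow(X), 1L)
  for (l in L:1) {
    if (l < L) delta <- delta * (acts[[l + 1]] > 0)
    delta <- delta %*% t(object$W[[l]])
  }
  delta
}
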