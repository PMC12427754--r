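test_that("background selection follows the per-family policy", {
  set.seed(1)
  tr <- matrix(rnorm(120 * 5), 120, 5, dimnames = list(NULL, paste0("g", 1:5)))
  for (fam in c("LR", "XGB", "NN", "DNN")) {
    bg <- select_background(tr, fam)
    expect_identical(attr(bg, "background_spec"), "full_train")
    expect_equal(nrow(bg), 120)
  }
  for (fam in c("SVM", "RF", "DT")) {
    bg <- select_background(tr, fam, k = 50, seed = 2)
    expect_identical(attr(bg, "background_spec"), "k_representatives")
    expect_equal(nrow(bg), 50)
    # representatives are actual training rows
    expect_true(all(apply(bg, 1, function(r)
      any(colSums(abs(t(tr) - r)) < 1e-12))))
  }
  expect_warning(bg2 <- select_background(tr[1:20, ], "RF", k = 50),
                 "smaller")
  expect_equal(nrow(bg2), 20)
})

test_that("linear attributions equal brute-force Shapley values of the log-odds", {
  fx <- fit_small_model("LR", cohort = small_cohort(
    n_cancer = 80, n_control = 60, n_flagged = 0, n_genes = 6,
    n_informative = 3, seed = 31), seed = 31)
  model <- fx$model
  bg <- select_background(fx$expr, "LR")
  att <- compute_attributions(model, fx$expr[1:4, , drop = FALSE], bg)
  expect_identical(att$output_scale, "logit")
  cf <- as.numeric(stats::coef(model$classifier$fit))
  a0 <- cf[1]; beta <- cf[-1]
  Z <- apply_scaler(model$scaler, fx$expr)
  f_logit <- function(M) as.numeric(a0 + M %*% beta)
  for (i in 1:4) {
    oracle <- shapley_brute_force(f_logit, Z[i, ], Z)
    expect_equal(unname(att$values[i, ]), oracle$phi, tolerance = 1e-8)
  }
  expect_equal(att$base_value, mean(f_logit(Z)), tolerance = 1e-10)
  # additivity: contributions + base reconstruct the sample's log-odds
  expect_equal(unname(rowSums(att$values) + att$base_value),
               f_logit(Z[1:4, , drop = FALSE]), tolerance = 1e-8)
})

test_that("tree attributions equal brute-force Shapley values of the tree game", {
  co <- small_cohort(n_cancer = 90, n_control = 60, n_flagged = 0,
                     n_genes = 6, n_informative = 3, seed = 32)
  meta <- exclude_flagged(co$metadata)
  expr <- co$expression[meta$sample_id, ]
  cfg <- model_config("XGB", n_search_iters = 1, cv_folds = 3, seed = 5,
                      search_space = list(nrounds = 15L, max_depth = 3L,
                                          eta = 0.3, subsample = 1,
                                          colsample_bytree = 1))
  model <- tune_and_fit(build_model(cfg), expr, meta$label)
  bg <- select_background(expr, "XGB")
  att <- compute_attributions(model, expr[1:3, , drop = FALSE], bg)
  Z <- apply_scaler(model$scaler, expr[1:3, , drop = FALSE])
  for (i in 1:3) {
    oracle <- xgb_shapley_brute_force(model$classifier$fit, Z[i, ])
    expect_equal(unname(att$values[i, ]), oracle$phi, tolerance = 1e-5)
  }
  # additivity against the booster's margin output
  marg <- predict(model$classifier$fit, xgboost::xgb.DMatrix(as.matrix(Z)),
                  outputmargin = TRUE)
  expect_equal(unname(rowSums(att$values)) + att$base_value, marg,
               tolerance = 1e-5)
})

test_that("kernel estimator recovers exact Shapley values when enumeration fits", {
  # nonlinear toy game, exact enumeration path (2^5 - 2 = 30 coalitions)
  set.seed(7)
  B <- matrix(rnorm(10 * 5), 10, 5)
  Z <- matrix(rnorm(3 * 5), 3, 5)
  f <- function(M) stats::plogis(M[, 1] * M[, 2] + 0.5 * M[, 3] - M[, 4]^2)
  ks <- tepmced:::kernel_shap(f, Z, B, nsim = 512, seed = 1)
  for (i in 1:3) {
    oracle <- shapley_brute_force(f, Z[i, ], B)
    expect_equal(unname(ks$values[i, ]), oracle$phi, tolerance = 1e-7)
    expect_equal(ks$base_value, oracle$base_value, tolerance = 1e-10)
  }
  # local accuracy by construction
  expect_equal(unname(rowSums(ks$values)) + ks$base_value,
               as.numeric(f(Z)), tolerance = 1e-7)
  # constant model: every attribution is zero
  ks0 <- tepmced:::kernel_shap(function(M) rep(0.3, nrow(M)), Z, B,
                               nsim = 512, seed = 1)
  expect_equal(unname(ks0$values), matrix(0, 3, 5), tolerance = 1e-10)
})

test_that("kernel-backend pipeline attributions match the brute-force oracle", {
  co <- small_cohort(n_cancer = 90, n_control = 60, n_flagged = 0,
                     n_genes = 5, n_informative = 3, seed = 33)
  meta <- exclude_flagged(co$metadata)
  expr <- co$expression[meta$sample_id, ]
  for (fam in c("DT", "SVM")) {
    cfg <- model_config(fam, n_search_iters = 1, cv_folds = 3, seed = 6)
    model <- tune_and_fit(build_model(cfg), expr, meta$label)
    bg <- select_background(expr, fam, k = 30, seed = 2)
    att <- compute_attributions(model, expr[1:2, , drop = FALSE], bg,
                                nsim = 512, seed = 3)
    expect_identical(att$output_scale, "probability")
    expect_identical(att$background_spec, "k_representatives")
    Zb <- apply_scaler(model$scaler, bg)
    Zx <- apply_scaler(model$scaler, expr[1:2, , drop = FALSE])
    f <- function(M) {
      colnames(M) <- colnames(expr)
      tepmced:::predict_prob(model$classifier, M)
    }
    for (i in 1:2) {
      oracle <- shapley_brute_force(f, Zx[i, ], as.matrix(Zb))
      expect_equal(unname(att$values[i, ]), oracle$phi, tolerance = 1e-6,
                   label = fam)
    }
  }
})

test_that("gradient attributions satisfy the completeness identity", {
  fx <- fit_small_model("NN", cohort = small_cohort(
    n_cancer = 90, n_control = 60, n_flagged = 0, n_genes = 8,
    n_informative = 4, seed = 34), seed = 34, n_search_iters = 1)
  model <- fx$model
  bg <- select_background(fx$expr, "NN")
  att <- compute_attributions(model, fx$expr[1:5, , drop = FALSE], bg,
                              ig_steps = 300, ig_background = 25, seed = 2)
  Z <- apply_scaler(model$scaler, fx$expr[1:5, , drop = FALSE])
  fx_logit <- predict(model$classifier$fit, as.matrix(Z), type = "logit")
  err <- abs(rowSums(att$values) + att$base_value - fx_logit)
  # midpoint-rule integration error; logits here span several units
  expect_lt(max(err), 0.05)
})

test_that("adaptive filtering lands in the target band or falls back honestly", {
  set.seed(12)
  V <- cbind(gauss = rnorm(5000),
             const = rep(0.2, 5000),
             heavy = c(stats::runif(4996), 97, 98, 99, 100))
  att <- structure(list(values = V, base_value = 0,
                        background_spec = "full_train",
                        output_scale = "logit"),
                   class = "attribution_set")
  att <- filter_outliers(att)
  rep <- att$filter_report
  g <- rep[rep$gene == "gauss", ]
  expect_identical(g$method, "iqr")
  expect_gte(g$fraction_zeroed, 0.05)
  expect_lte(g$fraction_zeroed, 0.10)
  # zeroed entries are exactly those outside the accepted bounds
  v <- V[, "gauss"]; fv <- att$filtered_values[, "gauss"]
  out <- v < g$lower | v > g$upper
  expect_true(all(fv[out] == 0))
  expect_identical(fv[!out], v[!out])
  # zero-IQR gene untouched
  c0 <- rep[rep$gene == "const", ]
  expect_identical(c0$method, "none")
  expect_identical(att$filtered_values[, "const"], V[, "const"])
  # uniform body + few extremes: no multiplier reaches the band
  h <- rep[rep$gene == "heavy", ]
  expect_identical(h$method, "percentile_fallback")
  pb <- stats::quantile(V[, "heavy"], c(0.01, 0.99), names = FALSE)
  expect_equal(c(h$lower, h$upper), pb)
  vh <- V[, "heavy"]
  expect_true(all(att$filtered_values[vh > pb[2] | vh < pb[1], "heavy"] == 0))
  expect_error(filter_outliers(structure(
    list(values = matrix(NA_real_, 2, 1)), class = "attribution_set")),
    "finite")
})

test_that("filtering multipliers are searched from least to most aggressive", {
  # a first-accepted k must leave larger multipliers outside the band
  set.seed(13)
  att <- structure(list(values = matrix(rnorm(3000), 1000, 3,
                                        dimnames = list(NULL, paste0("g", 1:3)))),
                   class = "attribution_set")
  att <- filter_outliers(att)
  for (j in 1:3) {
    r <- att$filter_report[j, ]
    if (r$method != "iqr") next
    v <- att$values[, j]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    larger <- seq(3, 0.5, by = -0.25)
    larger <- larger[larger > r$iqr_multiplier]
    for (k in larger) {
      fr <- mean(v < q[1] - k * iqr | v > q[2] + k * iqr)
      expect_false(fr >= 0.05 && fr <= 0.10)
    }
  }
})

test_that("global importance is the ordered mean absolute filtered attribution", {
  V <- rbind(c(1, -2, 0.5), c(-1, 2, 0.5), c(1, -2, -0.5), c(3, 2, 0.5))
  colnames(V) <- c("gA", "gB", "gC")
  att <- structure(list(values = V), class = "attribution_set")
  att$filtered_values <- V
  imp <- global_importance(att)
  expect_equal(unname(imp), c(2, 1.5, 0.5))
  expect_equal(names(imp), c("gB", "gA", "gC"))
  # deterministic tie-break by gene id
  V2 <- cbind(gZ = c(1, -1), gA = c(-1, 1))
  att2 <- structure(list(values = V2, filtered_values = V2),
                    class = "attribution_set")
  expect_equal(names(global_importance(att2)), c("gA", "gZ"))
  # zeroing can only shrink importance
  set.seed(14)
  V3 <- matrix(rt(4000, df = 2), 500, 8,
               dimnames = list(NULL, paste0("g", 1:8)))
  att3 <- filter_outliers(structure(list(values = V3),
                                    class = "attribution_set"))
  raw <- global_importance(att3, use_filtered = FALSE)
  flt <- global_importance(att3, use_filtered = TRUE)
  expect_true(all(flt[names(raw)] <= raw + 1e-12))
  expect_error(global_importance(structure(list(values = V3),
                                           class = "attribution_set")),
               "filter_outliers")
})

test_that("dependence data finds a planted interaction partner", {
  set.seed(15)
  n <- 400
  E <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("s%03d", 1:n), paste0("g", 1:4)))
  # attribution of g1 modulated multiplicatively by g2
  a1 <- E[, 1] * E[, 2]
  V <- cbind(g1 = a1, g2 = rnorm(n, 0, 0.1), g3 = rnorm(n, 0, 0.1),
             g4 = rnorm(n, 0, 0.1))
  rownames(V) <- rownames(E)
  att <- structure(list(values = V, base_value = 0),
                   class = "attribution_set")
  dd <- dependence_data(att, E, "g1", interaction = "auto")
  expect_identical(unique(dd$interaction_gene), "g2")
  expect_equal(dd$expression, unname(E[, "g1"]))
  expect_equal(dd$attribution, unname(a1))
  expect_equal(dd$interaction_expression, unname(E[, "g2"]))
  # explicit partner is honored; unknown genes error
  dd2 <- dependence_data(att, E, "g1", interaction = "g3")
  expect_identical(unique(dd2$interaction_gene), "g3")
  expect_error(dependence_data(att, E, "nope"), "unknown gene")
  expect_error(dependence_data(att, E, "g1", interaction = "nope"),
               "interaction gene")
})

test_that("local explanations rank by magnitude and reconstruct the margin", {
  fx <- fit_small_model("LR", cohort = small_cohort(
    n_cancer = 70, n_control = 50, n_flagged = 0, n_genes = 6,
    n_informative = 3, seed = 35), seed = 35)
  model <- fx$model
  bg <- select_background(fx$expr, "LR")
  att <- compute_attributions(model, fx$expr[1:2, , drop = FALSE], bg)
  sid <- rownames(att$values)[1]
  le <- local_explanation(att, sid, top_k = 3)
  expect_equal(nrow(le), 3)
  expect_true(all(diff(abs(le$attribution)) <= 1e-12))
  expect_setequal(le$gene[1:3],
                  names(sort(abs(att$values[sid, ]),
                             decreasing = TRUE))[1:3])
  # with top_k = p the signed sum plus base value is the log-odds
  le_all <- local_explanation(att, sid, top_k = 99)
  cf <- as.numeric(stats::coef(model$classifier$fit))
  z <- apply_scaler(model$scaler, fx$expr[sid, , drop = FALSE])
  expect_equal(sum(le_all$attribution) + attr(le_all, "base_value"),
               cf[1] + sum(cf[-1] * as.numeric(z)), tolerance = 1e-8)
  expect_error(local_explanation(att, "missing-id"), "unknown sample")
})
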