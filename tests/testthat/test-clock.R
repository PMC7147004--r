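std_design <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("g%03d", seq_len(p))))
  txclock:::standardize_columns(X)$X
}

test_that("lambda = 0 on a full-rank tall design reproduces least squares", {
  X <- std_design(50, 10, seed = 1)
  set.seed(2)
  y <- drop(X %*% rnorm(10)) + rnorm(50, 0, 0.5)
  yc <- y - mean(y)
  beta <- lasso_coordinate_descent(X, yc, 0, tol = 1e-10)
  ref <- lm.fit(X, yc)$coefficients
  expect_equal(as.vector(beta), unname(ref), tolerance = 1e-8)
})

test_that("lambda >= lambda_max yields the all-zero vector", {
  X <- std_design(40, 15, seed = 3)
  set.seed(4)
  y <- rnorm(40); yc <- y - mean(y)
  lmax <- lambda_max(X, yc)
  expect_equal(as.vector(lasso_coordinate_descent(X, yc, lmax)), rep(0, 15))
  expect_equal(as.vector(lasso_coordinate_descent(X, yc, lmax * 1.5)), rep(0, 15))
})

test_that("orthonormal designs recover the soft-threshold closed form exactly", {
  set.seed(5)
  n <- 40; p <- 10
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  X <- Q * sqrt(n)                       # X'X / n = I
  beta_true <- c(3, -2, 1.5, rep(0, p - 3))
  y <- drop(X %*% beta_true) + rnorm(n, 0, 0.3)
  yc <- y - mean(y)
  bols <- drop(crossprod(X, yc)) / n
  for (lam in c(0.05, 0.5, 1.5)) {
    beta <- lasso_coordinate_descent(X, yc, lam, tol = 1e-12)
    expected <- sign(bols) * pmax(abs(bols) - lam, 0)
    expect_equal(as.vector(beta), unname(expected), tolerance = 1e-10)
  }
})

test_that("returned fits satisfy the KKT conditions", {
  set.seed(6)
  for (i in 1:10) {
    X <- std_design(30, 50, seed = 600 + i)
    y <- rnorm(30); yc <- y - mean(y)
    lam <- runif(1, 0.05, 0.5) * lambda_max(X, yc)
    beta <- lasso_coordinate_descent(X, yc, lam, tol = 1e-8)
    expect_lte(lasso_kkt_violation(X, yc, beta, lam), 1e-6)
  }
})

test_that("coordinate descent agrees with glmnet at matched lambda", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  n <- 60; p <- 40
  X <- std_design(n, p, seed = 8)
  y <- drop(X[, 1:4] %*% c(2, -1, 1, 0.5)) + rnorm(n, 0, 0.5)
  yc <- y - mean(y)
  lam <- 0.2 * lambda_max(X, yc)
  beta <- lasso_coordinate_descent(X, yc, lam, tol = 1e-10)
  g <- glmnet::glmnet(X, yc, lambda = lam, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  expect_equal(as.vector(beta), unname(as.numeric(g$beta)), tolerance = 1e-5)
})

test_that("non-finite inputs and invalid lambda are rejected", {
  X <- std_design(10, 3, seed = 9)
  y <- rnorm(10)
  expect_error(lasso_coordinate_descent(X, c(y[-1], NA), 0.1), "non-finite")
  expect_error(lasso_coordinate_descent(X, y, -0.1), "lambda")
  expect_error(lasso_coordinate_descent(X, y[-1], 0.1), "length")
})

test_that("cross-validated lambda selection is deterministic and honors the grid", {
  X <- std_design(40, 20, seed = 10)
  set.seed(11)
  y <- drop(X[, 1:2] %*% c(1, -1)) + rnorm(40, 0, 0.3)
  one <- cv_select_lambda(X, y, k = 5, lambda_grid = 0.07, seed = 3)
  expect_equal(one$lambda_min, 0.07)

  f1 <- cv_select_lambda(X, y, k = 5, seed = 3)
  f2 <- cv_select_lambda(X, y, k = 5, seed = 3)
  expect_identical(f1$fold_assignments, f2$fold_assignments)
  expect_identical(f1$lambda_min, f2$lambda_min)
  expect_identical(f1$cv_mse_mean, f2$cv_mse_mean)
  f3 <- cv_select_lambda(X, y, k = 5, seed = 4)
  expect_false(identical(f1$fold_assignments, f3$fold_assignments))
  expect_error(cv_select_lambda(X, y, k = 1), "k >= 2")
})

test_that("cross-validation recovers a sparse true support", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 60; p <- 50
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("g%02d", 1:p)))
    y <- drop(X[, 1:3] %*% c(2, 2, 2)) + rnorm(n, 0, 1)
    fit <- cv_select_lambda(X, y, k = 5, seed = 1000 + s)
    support <- which(fit$coefficient_path[, fit$lambda_min_index] != 0)
    if (all(1:3 %in% support)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("a gene identical to age produces a zero-training-error clock", {
  set.seed(12)
  md <- tiny_metadata(n = 30, ages = runif(30, 3, 10))
  x <- matrix(rnorm(20 * 30, 7, 1), 20, 30,
              dimnames = list(sprintf("g%02d", 1:20), md$sample_id))
  x["g01", ] <- md$age_months
  model <- fit_clock(x, md, seed = 5)
  pr <- predict_age(model, x, md)
  expect_lt(mae(pr$predicted_age_months, pr$chronological_age_months), 1e-6)
  expect_true("g01" %in% names(model$coefficients))
})

test_that("permuted ages yield no spurious predictive signal", {
  ratios <- numeric(10)
  for (s in 1:10) {
    set.seed(2000 + s)
    n <- 60; p <- 100
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("g%03d", 1:p)))
    y <- sample(rep(c(3, 4, 6, 8, 10), length.out = n))  # ages with no link to X
    fit <- cv_select_lambda(X, y, k = 5, seed = s)
    ratios[s] <- fit$cv_mse_mean[fit$lambda_min_index] / var(y)
  }
  expect_gte(median(ratios), 0.8)
})

test_that("prediction follows the linear model, including imputation identity", {
  set.seed(13)
  md <- tiny_metadata(n = 20, ages = runif(20, 3, 10))
  x <- matrix(rnorm(30 * 20, 7, 1), 30, 20,
              dimnames = list(sprintf("g%02d", 1:30), md$sample_id))
  x["g01", ] <- md$age_months + rnorm(20, 0, 0.1)
  x["g02", ] <- 0.5 * md$age_months + rnorm(20, 0, 0.1)
  model <- fit_clock(x, md, seed = 6)
  genes <- names(model$coefficients)
  expect_gte(length(genes), 1)

  # intercept-only model predicts its intercept everywhere
  m0 <- clock_model(intercept = 6.5)
  expect_equal(predict_age(m0, x)$predicted_age_months, rep(6.5, 20))

  # training samples through their own model reproduce the refit MAE
  pr <- predict_age(model, x, md)
  A <- cbind(1, t(x[genes, , drop = FALSE]))
  refit_pred <- drop(A %*% c(model$intercept, model$coefficients))
  expect_equal(pr$predicted_age_months, unname(refit_pred), tolerance = 1e-10)

  # dropping one model gene under imputation == fixing it at its training mean
  g <- genes[1]
  x_dropped <- x[setdiff(rownames(x), g), , drop = FALSE]
  pr_imp <- predict_age(model, x_dropped, md,
                        missing_policy = "impute_training_mean",
                        missing_threshold = 1)
  x_fixed <- x
  x_fixed[g, ] <- model$standardization_params$mean[g]
  pr_fix <- predict_age(model, x_fixed, md)
  expect_equal(pr_imp$predicted_age_months, pr_fix$predicted_age_months,
               tolerance = 1e-12)
  expect_equal(unique(pr_imp$genes_missing_count), 1L)

  # beyond the missing threshold -> error naming genes
  x_none <- x[setdiff(rownames(x), genes), , drop = FALSE]
  expect_error(predict_age(model, x_none, md, missing_threshold = 0.2),
               "missing")
  expect_error(predict_age(model, x_dropped, md, missing_policy = "error"),
               g)
})

test_that("scaling ages scales predictions equivariantly", {
  set.seed(14)
  md <- tiny_metadata(n = 40, ages = runif(40, 3, 10))
  x <- matrix(rnorm(15 * 40, 7, 1), 15, 40,
              dimnames = list(sprintf("g%02d", 1:15), md$sample_id))
  x["g01", ] <- md$age_months + rnorm(40, 0, 0.05)
  x["g02", ] <- -0.8 * md$age_months + rnorm(40, 0, 0.05)
  md2 <- md; md2$age_months <- 2 * md$age_months
  m1 <- fit_clock(x, md, seed = 7, sweep_tol = 0, tol = 1e-9)
  m2 <- fit_clock(x, md2, seed = 7, sweep_tol = 0, tol = 1e-9)
  p1 <- predict_age(m1, x)$predicted_age_months
  p2 <- predict_age(m2, x)$predicted_age_months
  expect_equal(p2, 2 * p1, tolerance = 1e-6)
})

test_that("the clock recovers chronological age out-of-sample on unexposed samples", {
  rs <- numeric(10)
  for (s in 1:10) {
    ds <- generate_dataset(small_paper_config(seed = 400 + s,
                                              exposure_shift_months = 0))
    sham <- ds$metadata[ds$metadata$exposure_group == "sham", ]
    tr_idx <- txclock:::with_seed(s, sample(nrow(sham), 83))
    m <- suppressWarnings(fit_clock(ds$matrix, sham[tr_idx, ], seed = s))
    va <- sham[-tr_idx, ]
    pr <- predict_age(m, ds$matrix[, va$sample_id, drop = FALSE], va)
    rs[s] <- cor(pr$predicted_age_months, pr$chronological_age_months)
  }
  expect_true(all(rs >= 0.95))
})

test_that("empty support falls back to an intercept-only model", {
  set.seed(15)
  md <- tiny_metadata(n = 20, ages = runif(20, 3, 10))
  x <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10), md$sample_id))
  expect_warning(
    m <- fit_clock(x, md, seed = 8, lambda_grid = 100),  # huge penalty
    "intercept-only")
  expect_length(m$coefficients, 0)
  expect_equal(m$intercept, mean(md$age_months))
})

test_that("excluded genes never enter the model", {
  set.seed(16)
  md <- tiny_metadata(n = 30, ages = runif(30, 3, 10))
  x <- matrix(rnorm(10 * 30), 10, 30,
              dimnames = list(sprintf("g%02d", 1:10), md$sample_id))
  x["g01", ] <- md$age_months  # perfect predictor, but excluded
  x["g02", ] <- 0.7 * md$age_months + rnorm(30, 0, 0.2)
  m <- fit_clock(x, md, excluded_genes = "g01", seed = 9)
  expect_false("g01" %in% names(m$coefficients))
  expect_false("g01" %in% m$training_gene_universe)
})
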