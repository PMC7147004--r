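# The transcriptomic age predictor.
#
# Pipeline: standardize genes -> LASSO path by cyclic coordinate descent
# -> lambda chosen at minimum mean validation MSE over seeded 5-fold CV
# (ties toward the larger, sparser lambda) -> ordinary-least-squares refit
# of age on the selected genes at the raw log2 expression scale, so that
# coefficients read as months per log2 unit.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Column standardization with population (1/n) scale, the usual LASSO
# convention. Constant columns get scale 1 (their centered values are all
# zero, so their coefficients stay 0).
standardize_columns <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- sqrt(colMeans(Xc^2))
  s[s == 0] <- 1
  list(X = sweep(Xc, 2, s, "/"), mean = mu, sd = s)
}

#' Smallest lambda with an all-zero LASSO solution
#' @param X column-centered (or standardized) design, samples x genes.
#' @param y centered response.
#' @return `max_g |x_g' y| / n`.
#' @export
lambda_max <- function(X, y) {
  max(abs(crossprod(X, y))) / nrow(X)
}

#' Log-spaced lambda grid
#' @param X,y standardized design and centered response.
#' @param n_lambda grid size (default 100).
#' @param min_ratio smallest lambda as a fraction of [lambda_max()]
#'   (default 0.001).
#' @return descending numeric vector.
#' @export
make_lambda_grid <- function(X, y, n_lambda = 100, min_ratio = 0.001) {
  lmax <- lambda_max(X, y)
  if (lmax <= 0) return(rep(0, n_lambda))
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' LASSO solution by cyclic coordinate descent
#'
#' Minimizes `(1/2n) ||y - X beta||^2 + lambda ||beta||_1` by cyclic
#' coordinate descent with soft-thresholding and active-set iteration.
#' Convergence is declared when the KKT subgradient conditions hold within
#' `tol`; non-convergence is an error carrying the last iterate in the
#' condition's `beta` field.
#'
#' @param X numeric matrix, samples x genes, column-standardized (or at
#'   least centered); passed to the solver as-is.
#' @param y centered numeric response.
#' @param lambda non-negative penalty.
#' @param tol KKT tolerance (default 1e-8).
#' @param max_iter sweep budget (default 100000).
#' @param beta_init optional warm start.
#' @param sweep_tol optional additional stopping rule: also stop once a
#'   full coordinate sweep moves no coefficient by more than this (0,
#'   the default, disables it and convergence is purely KKT).
#' @return numeric coefficient vector (named by `colnames(X)`), with
#'   attributes `iterations` and `kkt_violation`.
#' @export
lasso_coordinate_descent <- function(X, y, lambda, tol = 1e-8,
                                     max_iter = 100000L,
                                     beta_init = NULL, sweep_tol = 0) {
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in X or y")
  }
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  fit <- .cd_lasso(X, as.numeric(y), lambda,
                   if (is.null(beta_init)) numeric(0) else as.numeric(beta_init),
                   tol, as.integer(max_iter), sweep_tol)
  if (!fit$converged) {
    cond <- simpleError(sprintf(
      "coordinate descent did not converge in %d sweeps (KKT violation %.3g)",
      fit$iterations, fit$kkt_violation))
    cond$beta <- setNames(fit$beta, colnames(X))
    stop(cond)
  }
  structure(setNames(fit$beta, colnames(X)),
            iterations = fit$iterations,
            kkt_violation = fit$kkt_violation)
}

#' Check KKT optimality of a LASSO solution
#' @param X,y design (samples x genes) and centered response.
#' @param beta coefficient vector.
#' @param lambda penalty used.
#' @return max subgradient violation (0 = exactly optimal).
#' @export
lasso_kkt_violation <- function(X, y, beta, lambda) {
  n <- nrow(X)
  g <- as.numeric(crossprod(X, y - X %*% beta)) / n
  viol_zero <- pmax(abs(g) - lambda, 0)
  viol_active <- abs(g - lambda * sign(beta))
  max(ifelse(beta == 0, viol_zero, viol_active))
}

#' Select lambda by k-fold cross-validation
#'
#' Fits a warm-started LASSO path per training fold (standardization
#' re-estimated within each fold) and picks the lambda with minimum mean
#' validation MSE; exact ties go to the larger (sparser) lambda.
#'
#' @param X raw samples x genes matrix.
#' @param y ages (months), uncentered.
#' @param k folds (default 5).
#' @param lambda_grid optional descending grid; computed from the full
#'   standardized data when `NULL`.
#' @param seed integer; fold assignment is deterministic given it.
#' @param n_lambda,min_ratio grid shape when `lambda_grid` is `NULL`.
#' @param tol,max_iter solver controls (KKT tolerance, sweep budget).
#' @param sweep_tol coefficient-stability stopping rule for the path
#'   fits: a fit also counts as converged when a full sweep moves no
#'   coefficient by more than this. The default 1e-4 (log2-unit scale,
#'   i.e. ~0.0001 months of predicted age per unit expression) is far
#'   below any difference that matters for MSE-based lambda selection
#'   and keeps repeated cross-validation affordable; set 0 for pure KKT
#'   convergence.
#' @return object of class `lasso_fit`: `lambda_grid`,
#'   `coefficient_path` (genes x lambda, on the standardized full-data
#'   scale), `cv_mse_mean`, `cv_mse_sd`, `lambda_min`, `lambda_min_index`,
#'   `fold_assignments`, `seed`, `standardization` (full-data params).
#' @export
cv_select_lambda <- function(X, y, k = 5, lambda_grid = NULL, seed = 1L,
                             n_lambda = 100, min_ratio = 0.001,
                             tol = 1e-6, max_iter = 100000L,
                             sweep_tol = 1e-4) {
  n <- nrow(X)
  if (k < 2 || n < k) stop("need n >= k >= 2 (n = ", n, ", k = ", k, ")")
  std <- standardize_columns(X)
  yc <- y - mean(y)
  if (is.null(lambda_grid)) {
    lambda_grid <- make_lambda_grid(std$X, yc, n_lambda, min_ratio)
  }
  if (is.unsorted(rev(lambda_grid))) {
    lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  }

  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  mse <- matrix(NA_real_, k, length(lambda_grid))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (sum(!tr) < 1) stop("fold ", f, " has no validation samples")
    std_f <- standardize_columns(X[tr, , drop = FALSE])
    ytr_mean <- mean(y[tr])
    pathf <- .cd_lasso_path(std_f$X, y[tr] - ytr_mean, lambda_grid,
                            tol, as.integer(max_iter), sweep_tol)
    Xval <- sweep(sweep(X[!tr, , drop = FALSE], 2, std_f$mean), 2,
                  std_f$sd, "/")
    pred <- ytr_mean + Xval %*% pathf$path
    mse[f, ] <- colMeans((pred - y[!tr])^2)
  }
  cv_mean <- colMeans(mse)
  cv_sd <- apply(mse, 2, sd)
  # grid is descending, so the first minimum is the largest lambda
  i_min <- which.min(cv_mean)

  path <- .cd_lasso_path(std$X, yc, lambda_grid, tol, as.integer(max_iter),
                         sweep_tol)
  structure(list(lambda_grid = lambda_grid,
                 coefficient_path = structure(
                   path$path, dimnames = list(colnames(X), NULL)),
                 cv_mse_mean = cv_mean,
                 cv_mse_sd = cv_sd,
                 lambda_min = lambda_grid[i_min],
                 lambda_min_index = i_min,
                 fold_assignments = folds,
                 seed = seed,
                 standardization = list(mean = std$mean, sd = std$sd)),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  supp <- sum(x$coefficient_path[, x$lambda_min_index] != 0)
  cat(sprintf(
    "lasso_fit: %d lambdas, lambda_min %.4g (%d nonzero), CV MSE %.4g\n",
    length(x$lambda_grid), x$lambda_min, supp,
    x$cv_mse_mean[x$lambda_min_index]))
  invisible(x)
}

#' Fit a transcriptomic age clock
#'
#' LASSO selection of predictor genes (lambda at minimum 5-fold CV MSE)
#' followed by an OLS refit of age on the selected genes at the raw log2
#' scale. An empty selection falls back to an intercept-only model with a
#' warning; a singular refit is ridge-stabilized (epsilon = 1e-8) with a
#' warning.
#'
#' @param matrix expression matrix (genes x samples) restricted or
#'   restrictable to the training samples.
#' @param metadata metadata rows for the training samples (needs
#'   `sample_id`, `age_months`).
#' @param excluded_genes gene ids removed from the selection universe.
#' @param k CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param n_lambda,min_ratio,tol,max_iter,sweep_tol passed to
#'   [cv_select_lambda()].
#' @param lambda_grid optional explicit grid.
#' @return a [clock_model()] (its `standardization_params` hold the
#'   training mean/sd of the selected genes; means double as imputation
#'   values for genes missing at prediction time).
#' @export
fit_clock <- function(matrix, metadata, excluded_genes = character(0),
                      k = 5, seed = 1L, n_lambda = 100, min_ratio = 0.001,
                      tol = 1e-6, max_iter = 100000L, lambda_grid = NULL,
                      sweep_tol = 1e-4) {
  validate_metadata(metadata)
  missing_s <- setdiff(metadata$sample_id, colnames(matrix))
  if (length(missing_s) > 0) {
    stop("training samples absent from matrix: ",
         paste(head(missing_s, 5), collapse = ", "))
  }
  genes <- setdiff(rownames(matrix), excluded_genes)
  X <- t(matrix[genes, metadata$sample_id, drop = FALSE])
  y <- metadata$age_months
  if (length(unique(y)) < 2) stop("need >= 2 distinct training ages")

  fit <- cv_select_lambda(X, y, k = k, lambda_grid = lambda_grid,
                          seed = seed, n_lambda = n_lambda,
                          min_ratio = min_ratio, tol = tol,
                          max_iter = max_iter, sweep_tol = sweep_tol)
  support <- genes[fit$coefficient_path[, fit$lambda_min_index] != 0]

  if (length(support) == 0) {
    warning("empty support at lambda_min; falling back to intercept-only model")
    return(clock_model(intercept = mean(y),
                       coefficients = numeric(0),
                       lambda_selected = fit$lambda_min,
                       training_gene_universe = genes,
                       training_sample_count = nrow(X),
                       lambda_grid = fit$lambda_grid))
  }

  A <- cbind(`(Intercept)` = 1, X[, support, drop = FALSE])
  ls <- lm.fit(A, y)
  if (ls$rank < ncol(A) || anyNA(ls$coefficients)) {
    warning("singular OLS refit; using ridge-stabilized solve (eps = 1e-8)")
    AtA <- crossprod(A) + diag(1e-8, ncol(A))
    cf <- drop(solve(AtA, crossprod(A, y)))
  } else {
    cf <- ls$coefficients
  }
  beta <- cf[-1]
  keep <- beta != 0
  clock_model(
    intercept = unname(cf[1]),
    coefficients = beta[keep],
    lambda_selected = fit$lambda_min,
    training_gene_universe = genes,
    training_sample_count = nrow(X),
    standardization_params = list(
      mean = fit$standardization$mean[support][keep],
      sd = fit$standardization$sd[support][keep]),
    lambda_grid = fit$lambda_grid)
}

#' Predict transcriptomic age
#'
#' `predicted = intercept + sum(coef_g * x_gs)`. Model genes absent from
#' the matrix are handled per `missing_policy`: with
#' `"impute_training_mean"` (default) the gene is fixed at its training
#' mean provided the missing fraction does not exceed
#' `missing_threshold`; with `"error"` any missing gene is an error.
#'
#' @param model a [clock_model()].
#' @param matrix expression matrix (genes x samples, log2).
#' @param metadata optional metadata supplying chronological ages for
#'   delta age.
#' @param missing_policy `"impute_training_mean"` or `"error"`.
#' @param missing_threshold max tolerated missing fraction of model genes
#'   (default 0.2).
#' @return data.frame: `sample_id`, `predicted_age_months`,
#'   `chronological_age_months`, `delta_age_months`,
#'   `genes_missing_count`.
#' @export
predict_age <- function(model, matrix, metadata = NULL,
                        missing_policy = c("impute_training_mean", "error"),
                        missing_threshold = 0.2) {
  missing_policy <- match.arg(missing_policy)
  validate_clock_model(model)
  genes <- names(model$coefficients)
  present <- intersect(genes, rownames(matrix))
  absent <- setdiff(genes, present)
  if (length(absent) > 0) {
    frac <- length(absent) / length(genes)
    if (missing_policy == "error" || frac > missing_threshold) {
      stop(sprintf("%d/%d model genes missing from matrix: %s",
                   length(absent), length(genes),
                   paste(head(absent, 10), collapse = ", ")))
    }
  }
  pred <- rep(model$intercept, ncol(matrix))
  if (length(present) > 0) {
    cf <- model$coefficients[present]
    pred <- pred + drop(crossprod(matrix[present, , drop = FALSE], cf))
  }
  if (length(absent) > 0) {
    mu <- model$standardization_params$mean[absent]
    if (anyNA(mu) || length(mu) != length(absent)) {
      stop("no training means recorded for missing gene(s): ",
           paste(head(absent, 10), collapse = ", "))
    }
    pred <- pred + sum(model$coefficients[absent] * mu)
  }
  out <- data.frame(sample_id = colnames(matrix),
                    predicted_age_months = unname(pred),
                    chronological_age_months = NA_real_,
                    delta_age_months = NA_real_,
                    genes_missing_count = length(absent),
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    idx <- match(out$sample_id, metadata$sample_id)
    out$chronological_age_months <- metadata$age_months[idx]
    out$delta_age_months <-
      out$predicted_age_months - out$chronological_age_months
  }
  out
}
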