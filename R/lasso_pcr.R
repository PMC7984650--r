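#' Fit a sparsity-constrained principal component regression (LASSO-PCR)
#'
#' The single-channel estimator. Features are centered by their training
#' means and decomposed by an economy SVD, `X = U S V'`; the response is
#' regressed on the component scores `Z = U S` under an L1 penalty,
#'
#'   `beta_hat = argmin_beta (1/n) ||y - Z beta||^2 + lambda ||beta||_1`,
#'
#' and the fitted coefficients are projected back to feature space as the
#' weight map `w_hat = V beta_hat`, so that predictions are
#' `(X_new - means) w_hat + intercept`. Because the columns of `Z` are
#' orthogonal, the penalized solution is available in closed form by
#' soft-thresholding each component's least-squares coefficient; the fit is
#' exact, not iterative. The per-observation normalization of the objective
#' makes the fit invariant to duplicating rows.
#'
#' The penalty is chosen on a decreasing grid by inner k-fold
#' cross-validation minimizing mean squared error, with the PCA refit inside
#' every fold so no held-out row touches any part of the fit. The same inner
#' folds produce out-of-fold (prevalidated) training predictions at the
#' selected penalty, the meta-features consumed by [fit_stacked()]. The
#' final model is refit on all provided rows at the selected penalty.
#'
#' All `min(n-1, p)` components are retained (the L1 step performs the
#' selection), except numerically null directions (singular value below
#' `1e-8` times the largest), which are dropped.
#'
#' @param x Numeric matrix, subjects by features.
#' @param y Numeric response vector, one value per row of `x`.
#' @param lambda_grid Optional decreasing vector of penalty values. By
#'   default, 30 log-spaced values from the smallest penalty that zeroes all
#'   coefficients (`lambda_max = 2 max|Z'y| / n`) down to
#'   `lambda_min_ratio * lambda_max`. A single-value grid fixes the penalty
#'   and skips selection. `0` is allowed and gives the least-squares fit in
#'   the component space.
#' @param inner_folds Number of inner CV folds (default 5).
#' @param seed Integer seed controlling the inner fold assignment.
#' @param nlambda,lambda_min_ratio Grid resolution and extent when
#'   `lambda_grid` is `NULL`.
#' @param compute_oof If `TRUE`, also run the inner folds when the grid has a
#'   single value, so out-of-fold predictions are returned.
#' @return An object of class `lasso_pcr` with elements `column_means`,
#'   `v` (principal axes, features x components), `singular_values`, `beta`
#'   (component coefficients), `lambda`, `lambda_grid`, `cv_mse`,
#'   `intercept` (training mean of `y`), `weight_map` (`V beta`), `foldid`
#'   and `oof` (out-of-fold training predictions at the selected penalty, or
#'   `NULL` when no folds were run).
#' @seealso [predict.lasso_pcr()], [out_of_fold_predictions()],
#'   [encoding_pattern()]
#' @export
#' @examples
#' x <- matrix(rnorm(200), 20, 10)
#' y <- x[, 1] - x[, 2] + rnorm(20, sd = 0.1)
#' fit <- fit_lasso_pcr(x, y, seed = 1)
#' cor(predict(fit, x), y)
fit_lasso_pcr <- function(x, y, lambda_grid = NULL, inner_folds = 5L,
                          seed = NULL, nlambda = 30L,
                          lambda_min_ratio = 1e-3, compute_oof = TRUE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) stop("length(y) != nrow(x)")
  if (n < 2L) stop("need at least 2 rows")
  stopifnot_finite(x, "x"); stopifnot_finite(y, "y")
  if (!is.null(lambda_grid)) {
    if (length(lambda_grid) == 0L) stop("empty lambda grid")
    if (any(lambda_grid < 0)) stop("negative penalty in lambda grid")
    lambda_grid <- sort(unique(as.numeric(lambda_grid)), decreasing = TRUE)
  }

  full <- pcr_basis(x)
  yc <- y - mean(y)
  cvec <- drop(crossprod(full$z, yc))

  if (is.null(lambda_grid)) {
    lambda_max <- if (length(cvec)) 2 * max(abs(cvec)) / n else 1
    if (lambda_max <= 0) lambda_max <- 1e-8
    lambda_grid <- exp(seq(log(lambda_max),
                           log(lambda_max * lambda_min_ratio),
                           length.out = nlambda))
  }

  foldid <- NULL; cv_mse <- NULL; oof <- NULL
  run_folds <- inner_folds >= 2L && n >= inner_folds &&
    (length(lambda_grid) > 1L || isTRUE(compute_oof))
  if (length(lambda_grid) > 1L && !run_folds)
    stop("cannot select among ", length(lambda_grid),
         " penalties without inner folds")

  if (run_folds) {
    foldid <- assign_folds(n, inner_folds, seed)
    preds <- matrix(NA_real_, n, length(lambda_grid))
    for (f in seq_len(inner_folds)) {
      in_f <- foldid == f
      sub <- pcr_basis(x[!in_f, , drop = FALSE])
      yf <- y[!in_f]
      cf <- drop(crossprod(sub$z, yf - mean(yf)))
      zt <- sweep(x[in_f, , drop = FALSE], 2L, sub$means) %*% sub$v
      for (l in seq_along(lambda_grid)) {
        b <- soft_threshold_scores(cf, sub$d2, lambda_grid[l], sum(!in_f))
        preds[in_f, l] <- drop(zt %*% b) + mean(yf)
      }
    }
    cv_mse <- colMeans((preds - y)^2)
    sel <- which.min(cv_mse)   # grid is decreasing: ties favor more shrinkage
    oof <- preds[, sel]
    lambda <- lambda_grid[sel]
  } else {
    lambda <- lambda_grid[1L]
  }

  beta <- soft_threshold_scores(cvec, full$d2, lambda, n)
  structure(
    list(column_means = full$means,
         v = full$v,
         singular_values = full$d,
         beta = beta,
         lambda = lambda,
         lambda_grid = lambda_grid,
         cv_mse = cv_mse,
         intercept = mean(y),
         weight_map = drop(full$v %*% beta),
         n_components = length(beta),
         foldid = foldid,
         oof = oof,
         n_train = n),
    class = "lasso_pcr")
}

# Centered economy SVD basis of a feature matrix: principal axes V, scores
# Z = US, squared singular values. Numerically null components dropped.
pcr_basis <- function(x, rank_tol = 1e-8) {
  n <- nrow(x)
  means <- colMeans(x)
  xc <- sweep(x, 2L, means)
  k <- min(n - 1L, ncol(x))
  sv <- svd(xc, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  keep <- if (length(d) && d[1L] > 0) d > d[1L] * rank_tol else logical(length(d))
  d <- d[keep]
  z <- sv$u[, keep, drop = FALSE] %*% diag(d, nrow = length(d))
  list(means = means, v = sv$v[, keep, drop = FALSE], d = d, d2 = d^2, z = z)
}

# Exact minimizer of (1/n)||yc - Z b||^2 + lambda ||b||_1 for orthogonal Z
# with Z'Z = diag(d2) and cvec = Z'yc.
soft_threshold_scores <- function(cvec, d2, lambda, n) {
  if (!length(cvec)) return(numeric(0))
  thr <- n * lambda / 2
  sign(cvec) * pmax(abs(cvec) - thr, 0) / d2
}

#' Predict from a fitted LASSO-PCR model
#'
#' @param object A `lasso_pcr` fit.
#' @param newdata Matrix with the same feature columns as the training data.
#' @param ... Unused.
#' @return Numeric vector `(newdata - column_means) %*% weight_map +
#'   intercept`.
#' @export
predict.lasso_pcr <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$column_means))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$column_means))
  drop(sweep(newdata, 2L, object$column_means) %*% object$weight_map) +
    object$intercept
}

#' @export
print.lasso_pcr <- function(x, ...) {
  cat("<lasso_pcr> ", length(x$column_means), " features, ",
      x$n_components, " components, lambda = ", signif(x$lambda, 4),
      ", ", sum(x$beta != 0), " nonzero coefficients\n", sep = "")
  invisible(x)
}

#' Out-of-fold training predictions from a LASSO-PCR model
#'
#' Partitions the rows into `k` folds (deterministically under `seed`) and
#' returns, for every row, a prediction produced by a model whose training
#' data excluded that row, at the penalty selected by the same k-fold CV.
#' These prevalidated predictions are the unbiased meta-features used at the
#' stacking level.
#'
#' @inheritParams fit_lasso_pcr
#' @param k Number of folds; `k = nrow(x)` gives leave-one-out.
#' @return Numeric vector with one out-of-fold prediction per row.
#' @export
out_of_fold_predictions <- function(x, y, k = 5L, lambda_grid = NULL,
                                    seed = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (k < 2L) stop("need at least 2 folds")
  if (k > nrow(x)) stop("more folds than rows")
  fit <- fit_lasso_pcr(x, y, lambda_grid = lambda_grid, inner_folds = k,
                       seed = seed, compute_oof = TRUE)
  fit$oof
}
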