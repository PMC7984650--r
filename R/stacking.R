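#' Assemble per-channel predictions into a meta-feature matrix
#'
#' Column `j` holds channel `j`'s predicted responses. Training rows should
#' be out-of-fold predictions (see [out_of_fold_predictions()]); test rows
#' are ordinary fitted-model predictions.
#'
#' @param per_channel_predictions List of equal-length numeric vectors.
#' @param channel_names Unique names, one per vector; defaults to the list's
#'   names.
#' @return An object of class `meta_matrix` with elements `matrix`
#'   (subjects x channels) and `channel_names`.
#' @export
build_meta_matrix <- function(per_channel_predictions,
                              channel_names = names(per_channel_predictions)) {
  if (length(per_channel_predictions) == 0L) stop("no prediction vectors")
  if (is.null(channel_names) ||
      length(channel_names) != length(per_channel_predictions))
    stop("channel_names must name every prediction vector")
  if (anyDuplicated(channel_names)) stop("duplicate channel names")
  lens <- lengths(per_channel_predictions)
  if (length(unique(lens)) != 1L)
    stop("prediction vectors differ in length: ",
         paste(unique(lens), collapse = " vs "))
  m <- do.call(cbind, lapply(per_channel_predictions, as.numeric))
  colnames(m) <- channel_names
  structure(list(matrix = m, channel_names = as.character(channel_names)),
            class = "meta_matrix")
}

as_meta <- function(x) {
  if (inherits(x, "meta_matrix")) return(x)
  if (is.matrix(x)) return(structure(list(matrix = x,
                                          channel_names = colnames(x)),
                                     class = "meta_matrix"))
  stop("expected a meta_matrix or matrix")
}

#' Fit the level-2 non-negative LASSO over stacked channel predictions
#'
#' Learns non-negative weights over the channels' out-of-fold predictions:
#'
#'   `min_{b >= 0} (1/n) ||y - a - M b||^2 + lambda sum(b)`
#'
#' The L1 penalty shrinks redundant channels to exactly zero; the
#' non-negativity constraint keeps surviving weights interpretable as
#' channel contributions. Meta-features are used on their natural scale (the
#' response's units); the intercept is unpenalized. The penalty is selected
#' on a decreasing grid by inner k-fold cross-validated mean squared error,
#' then the model is refit on all rows. The solver is cyclic coordinate
#' descent with warm starts along the grid, fixed column order breaking ties
#' between duplicated columns.
#'
#' @param meta_train A [build_meta_matrix()] object (or plain matrix) of
#'   training out-of-fold predictions.
#' @param y_train Response values for the training rows.
#' @param lambda_grid Optional decreasing penalty grid; default 30
#'   log-spaced values from the smallest penalty zeroing all coefficients.
#' @param inner_folds Inner CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param nlambda,lambda_min_ratio Default grid resolution and extent.
#' @return Object of class `stacked_model` with `channel_names`,
#'   `coefficients` (named, all `>= 0`), `intercept`, `lambda`,
#'   `lambda_grid` and `cv_mse`.
#' @export
fit_stacked <- function(meta_train, y_train, lambda_grid = NULL,
                        inner_folds = 5L, seed = NULL, nlambda = 30L,
                        lambda_min_ratio = 1e-3) {
  meta <- as_meta(meta_train)
  m <- meta$matrix
  n <- nrow(m)
  if (length(y_train) != n) stop("length(y_train) != nrow(meta matrix)")
  stopifnot_finite(m, "meta matrix"); stopifnot_finite(y_train, "y_train")
  if (!is.null(lambda_grid)) {
    if (length(lambda_grid) == 0L) stop("empty lambda grid")
    if (any(lambda_grid < 0)) stop("negative penalty")
    lambda_grid <- sort(unique(as.numeric(lambda_grid)), decreasing = TRUE)
  }

  mc <- sweep(m, 2L, colMeans(m))
  yc <- y_train - mean(y_train)
  gram <- crossprod(mc)
  cvec <- drop(crossprod(mc, yc))

  if (is.null(lambda_grid)) {
    lambda_max <- 2 * max(cvec, 0) / n  # entry condition for b_j >= 0
    if (lambda_max <= 0) lambda_max <- 2 * max(abs(cvec), 1e-8) / n
    lambda_grid <- exp(seq(log(lambda_max),
                           log(lambda_max * lambda_min_ratio),
                           length.out = nlambda))
  }

  foldid <- NULL; cv_mse <- NULL
  if (length(lambda_grid) > 1L) {
    if (n < 2L * inner_folds)
      stop("need at least ", 2L * inner_folds, " rows for ", inner_folds,
           "-fold penalty selection")
    foldid <- assign_folds(n, inner_folds, seed)
    preds <- matrix(NA_real_, n, length(lambda_grid))
    for (f in seq_len(inner_folds)) {
      in_f <- foldid == f
      mf <- m[!in_f, , drop = FALSE]
      yf <- y_train[!in_f]
      mfc <- sweep(mf, 2L, colMeans(mf))
      path <- nonneg_lasso_path(crossprod(mfc), drop(crossprod(mfc, yf - mean(yf))),
                                lambda_grid, sum(!in_f))
      icpt <- mean(yf) - drop(colMeans(mf) %*% path)
      preds[in_f, ] <- m[in_f, , drop = FALSE] %*% path +
        rep(icpt, each = sum(in_f))
    }
    cv_mse <- colMeans((preds - y_train)^2)
    lambda <- lambda_grid[which.min(cv_mse)]
  } else {
    lambda <- lambda_grid[1L]
  }

  beta <- drop(nonneg_lasso_path(gram, cvec, lambda, n))
  names(beta) <- meta$channel_names
  structure(
    list(channel_names = meta$channel_names,
         coefficients = beta,
         intercept = mean(y_train) - sum(colMeans(m) * beta),
         lambda = lambda,
         lambda_grid = lambda_grid,
         cv_mse = cv_mse,
         foldid = foldid),
    class = "stacked_model")
}

# Cyclic coordinate descent for min (1/n)||yc - Mc b||^2 + lambda sum(b),
# b >= 0, given gram = Mc'Mc and cvec = Mc'yc. Returns a k x length(lambdas)
# matrix of solutions, warm-started along the (decreasing) grid.
nonneg_lasso_path <- function(gram, cvec, lambdas, n,
                              tol = 1e-12, max_iter = 10000L) {
  k <- length(cvec)
  out <- matrix(0, k, length(lambdas))
  beta <- numeric(k)
  scale <- max(abs(cvec), 1)
  for (l in seq_along(lambdas)) {
    thr <- n * lambdas[l] / 2
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (j in seq_len(k)) {
        if (gram[j, j] <= 0) next
        resid_cor <- cvec[j] - sum(gram[j, ] * beta) + gram[j, j] * beta[j]
        bj <- max(0, (resid_cor - thr) / gram[j, j])
        delta <- max(delta, abs(bj - beta[j]) * sqrt(gram[j, j]))
        beta[j] <- bj
      }
      if (delta <= tol * scale) break
    }
    # soft-thresholding yields exact zeros; clear sub-tolerance fp residue
    # (e.g. from exactly duplicated columns) so shrunk channels report 0
    beta[beta < 1e-9 * max(1, beta)] <- 0
    out[, l] <- beta
  }
  out
}

#' Predict from a stacked model
#'
#' @param object A `stacked_model`.
#' @param meta_test A `meta_matrix` (or matrix) whose channel order matches
#'   the model's.
#' @param ... Unused.
#' @return `meta_test %*% coefficients + intercept`.
#' @export
predict.stacked_model <- function(object, meta_test, ...) {
  meta <- as_meta(meta_test)
  if (!is.null(meta$channel_names) &&
      !identical(meta$channel_names, object$channel_names))
    stop("channel names of meta matrix do not match the model (",
         paste(meta$channel_names, collapse = ","), " vs ",
         paste(object$channel_names, collapse = ","), ")")
  drop(meta$matrix %*% object$coefficients) + object$intercept
}

#' @rdname predict.stacked_model
#' @export
predict_stacked <- function(object, meta_test, ...)
  predict.stacked_model(object, meta_test, ...)

#' @export
print.stacked_model <- function(x, ...) {
  cat("<stacked_model> lambda =", signif(x$lambda, 4), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Run the full two-level protocol on one train/test split
#'
#' Executes the complete workflow for one partition: (optional) train-only
#' residualization of the response on a neuroimaging confounder, per-channel
#' LASSO-PCR with inner 5-fold penalty selection and out-of-fold training
#' predictions, test-set predictions from the refit channel models, a
#' non-negative L1 stacked fit on the out-of-fold matrix, and final stacked
#' test predictions. Features with zero variance on the training rows are
#' discarded per channel before fitting. No test-set response or feature row
#' influences any fitted parameter.
#'
#' @param channels List of [feature_channel()] objects sharing subject
#'   order.
#' @param y Response vector over all subjects.
#' @param train_idx,test_idx Disjoint integer index vectors.
#' @param icv Optional per-subject confounder (intracranial volume) to
#'   partial out of the response with train-only coefficients.
#' @param inner_folds Inner CV folds at both levels (default 5).
#' @param seed Integer seed; all fold assignments derive from it.
#' @return Object of class `two_level_fit`: `channel_models`,
#'   `channel_test_predictions` (matrix, one column per channel),
#'   `stacked_test_predictions`, `stacked_model`, `meta_train`, `meta_test`,
#'   and the (possibly residualized) `y_train`, `y_test`.
#' @export
run_two_level <- function(channels, y, train_idx, test_idx, icv = NULL,
                          inner_folds = 5L, seed = NULL) {
  channels <- as_channel_list(channels)
  train_idx <- as.integer(train_idx); test_idx <- as.integer(test_idx)
  if (length(intersect(train_idx, test_idx)))
    stop("train and test indices overlap")
  y_train <- y[train_idx]; y_test <- y[test_idx]
  if (!is.null(icv)) {
    adj <- residualize_response(y_train, y_test, icv[train_idx], icv[test_idx])
    y_train <- adj$y_train; y_test <- adj$y_test
  }

  l1_seed <- derive_seed(seed, "level1")
  oofs <- list(); test_preds <- list(); models <- list()
  for (ch in channels) {
    xtr <- ch$matrix[train_idx, , drop = FALSE]
    keep <- apply(xtr, 2L, stats::var) > 0
    if (!any(keep)) stop("channel '", ch$name,
                         "' has no variable features on the training rows")
    fit <- fit_lasso_pcr(xtr[, keep, drop = FALSE], y_train,
                         inner_folds = inner_folds, seed = l1_seed,
                         compute_oof = TRUE)
    models[[ch$name]] <- fit
    oofs[[ch$name]] <- fit$oof
    test_preds[[ch$name]] <-
      predict(fit, ch$matrix[test_idx, keep, drop = FALSE])
  }

  meta_train <- build_meta_matrix(oofs)
  meta_test <- build_meta_matrix(test_preds)
  stack <- fit_stacked(meta_train, y_train, inner_folds = inner_folds,
                       seed = derive_seed(seed, "level2"))
  structure(
    list(channel_models = models,
         channel_test_predictions = meta_test$matrix,
         stacked_test_predictions = predict(stack, meta_test),
         stacked_model = stack,
         meta_train = meta_train,
         meta_test = meta_test,
         y_train = y_train,
         y_test = y_test),
    class = "two_level_fit")
}
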