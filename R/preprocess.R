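#' Vectorize the strict upper triangle of a symmetric matrix
#'
#' Connectivity matrices (e.g. Fisher z-transformed correlation matrices over
#' p parcels) are reduced to their p(p-1)/2 off-diagonal values. The diagonal
#' is excluded (self-correlation is uninformative and infinite after the z
#' transform). Order is row-major over the strict upper triangle:
#' (1,2), (1,3), ..., (1,p), (2,3), ..., (p-1,p).
#'
#' @param m Square numeric matrix, symmetric within `tol`.
#' @param tol Symmetry tolerance.
#' @return Numeric vector of length `p*(p-1)/2`.
#' @seealso [devectorize_upper_triangle()] for the inverse.
#' @export
#' @examples
#' m <- matrix(0, 3, 3); m[upper.tri(m)] <- 1:3; m <- m + t(m)
#' vectorize_upper_triangle(m)
vectorize_upper_triangle <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("input must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop("matrix is not symmetric within tolerance ", tol)
  t(m)[lower.tri(m)]  # row-major strict upper triangle
}

#' Rebuild a symmetric zero-diagonal matrix from its upper-triangle vector
#'
#' @param v Vector in the row-major order produced by
#'   [vectorize_upper_triangle()].
#' @param p Number of rows/columns of the target matrix; inferred from
#'   `length(v)` when omitted.
#' @return A `p x p` symmetric matrix with zero diagonal.
#' @export
devectorize_upper_triangle <- function(v, p = NULL) {
  if (is.null(p)) {
    p <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (p != round(p)) stop("length ", length(v), " is not p*(p-1)/2 for integer p")
    p <- as.integer(round(p))
  }
  if (length(v) != p * (p - 1) / 2)
    stop("length mismatch: expected ", p * (p - 1) / 2, ", got ", length(v))
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- v   # fill column-major lower = row-major upper
  m <- t(m)
  m + t(m)
}

#' Drop zero-variance features from a channel
#'
#' Constant columns carry no predictive information and break scaling-based
#' post-processing, so they are discarded before fitting, with their labels
#' reported.
#'
#' @param channel A [feature_channel()].
#' @param tol Columns with variance `<= tol` are treated as constant.
#' @return List with `channel` (the reduced channel) and `dropped`
#'   (character vector of removed labels, possibly empty).
#' @export
drop_zero_variance <- function(channel, tol = 0) {
  stopifnot(inherits(channel, "feature_channel"))
  v <- apply(channel$matrix, 2L, stats::var)
  keep <- v > tol
  if (!any(keep)) stop("all columns of channel '", channel$name,
                       "' have zero variance")
  if (all(keep)) return(list(channel = channel, dropped = character(0)))
  groups <- channel$feature_groups
  if (!is.null(groups)) groups <- groups[names(groups) %in%
                                           channel$feature_labels[keep]]
  list(channel = feature_channel(channel$name,
                                 channel$matrix[, keep, drop = FALSE],
                                 channel$feature_labels[keep], groups),
       dropped = channel$feature_labels[!keep])
}

#' Residualize a response on a confounder using train-only coefficients
#'
#' Partials a neuroimaging confounder (typically intracranial volume) out of
#' the response by simple linear regression whose intercept and slope are
#' estimated on the training set only; test responses are then adjusted with
#' those same coefficients, so no test information ever enters the fit.
#'
#' @param y_train,y_test Response values for the training and test subjects.
#' @param conf_train,conf_test Confounder values, aligned with the responses.
#' @return List with `y_train`, `y_test` (residuals) and the fitted
#'   `intercept` and `slope`.
#' @export
residualize_response <- function(y_train, y_test, conf_train, conf_test) {
  if (length(y_train) != length(conf_train))
    stop("train response and confounder lengths differ")
  if (length(y_test) != length(conf_test))
    stop("test response and confounder lengths differ")
  if (length(y_train) < 3L) stop("need at least 3 training subjects")
  stopifnot_finite(c(y_train, conf_train, y_test, conf_test), "residualize_response inputs")
  if (stats::var(conf_train) <= 0) {
    warning("confounder has zero variance in the training set; ",
            "fitting intercept-only adjustment")
    a <- mean(y_train); b <- 0
  } else {
    b <- stats::cov(conf_train, y_train) / stats::var(conf_train)
    a <- mean(y_train) - b * mean(conf_train)
  }
  list(y_train = y_train - (a + b * conf_train),
       y_test  = y_test - (a + b * conf_test),
       intercept = a, slope = b)
}
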