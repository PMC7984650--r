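#' Transform decoding weights into an encoding pattern
#'
#' Backward-model weights can be large for features that only suppress
#' noise; multiplying by the training feature covariance turns them into
#' forward (encoding) loadings interpretable as feature-response
#' association: `A = Sigma_X w`. The response-variance factor is a scalar
#' for a single response and is omitted, so patterns are meaningful up to a
#' positive scale (and typically rescaled with [maxabs_rescale()]).
#'
#' For wide channels the covariance matrix is never materialized: the
#' pattern is computed as `Xc' (Xc w) / (n - 1)` with `Xc` the centered
#' training matrix.
#'
#' @param weight_map Numeric weight vector, one entry per feature (e.g.
#'   `fit$weight_map` of a [fit_lasso_pcr()] model).
#' @param x Training feature matrix (centered internally).
#' @param channel_name Optional label carried on the result.
#' @return Object of class `encoding_pattern` with `loadings`, `channel`,
#'   `feature_labels` and `rescaled = FALSE`.
#' @export
encoding_pattern <- function(weight_map, x, channel_name = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (length(weight_map) != ncol(x))
    stop("weight_map length (", length(weight_map),
         ") != feature count (", ncol(x), ")")
  if (nrow(x) < 2L) stop("need at least 2 rows to estimate a covariance")
  xc <- sweep(x, 2L, colMeans(x))
  a <- drop(crossprod(xc, xc %*% weight_map)) / (nrow(x) - 1)
  structure(list(loadings = a, channel = channel_name,
                 feature_labels = colnames(x), rescaled = FALSE,
                 ordering = "matches training feature columns"),
            class = "encoding_pattern")
}

#' Rescale loadings to the unit interval by maximum absolute value
#'
#' Divides by the largest absolute loading so values lie in `[-1, 1]`,
#' preserving zeros exactly (sparsity is not broken). All-zero input is
#' returned unchanged.
#'
#' @param loadings Numeric vector or an `encoding_pattern`.
#' @return Same shape as the input, rescaled.
#' @export
maxabs_rescale <- function(loadings) {
  if (inherits(loadings, "encoding_pattern")) {
    loadings$loadings <- maxabs_rescale(loadings$loadings)
    loadings$rescaled <- TRUE
    return(loadings)
  }
  if (length(loadings) == 0L) stop("empty loadings")
  m <- max(abs(loadings))
  if (m == 0) loadings else loadings / m
}

#' Region strength map from connectivity-link loadings
#'
#' Rebuilds the symmetric matrix of absolute link loadings from its
#' upper-triangle vector, keeps only the `top_fraction` largest absolute
#' link values (ties at the threshold kept), and sums over rows, giving a
#' per-region concentration of the strongest links.
#'
#' @param link_loadings Vector over region pairs in
#'   [vectorize_upper_triangle()] order.
#' @param n_regions Number of regions; inferred from the length if omitted.
#' @param top_fraction Fraction of links retained (default 0.01).
#' @return Numeric vector of per-region strengths.
#' @export
strength_map <- function(link_loadings, n_regions = NULL,
                         top_fraction = 0.01) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  m <- abs(devectorize_upper_triangle(link_loadings, n_regions))
  v <- abs(link_loadings)
  keep_n <- ceiling(top_fraction * length(v))
  thr <- sort(v, decreasing = TRUE)[keep_n]
  if (thr > 0) m[m < thr] <- 0
  rowSums(m)
}

#' Signed group averages of encoding loadings
#'
#' For each feature group (e.g. white-matter tract), the mean over its
#' strictly positive (or strictly negative) loadings. Groups with no
#' loading of the requested sign are flagged absent (`NA` mean); zeros
#' count as neither sign. Features missing from the grouping are ignored
#' and counted.
#'
#' @param pattern An `encoding_pattern` or a named numeric vector of
#'   loadings.
#' @param grouping Named character vector mapping feature label to group
#'   label. Defaults to the channel's `feature_groups` when `pattern` came
#'   from a grouped channel.
#' @param sign `"positive"` or `"negative"`.
#' @return Data frame with columns `group`, `mean_loading` (`NA` when the
#'   group has no loading of that sign), `n_sign` (features of that sign)
#'   and attribute `n_ungrouped`.
#' @export
group_average_loadings <- function(pattern, grouping,
                                   sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (inherits(pattern, "encoding_pattern")) {
    loadings <- pattern$loadings
    names(loadings) <- pattern$feature_labels
  } else loadings <- pattern
  if (is.null(names(loadings))) stop("loadings must carry feature labels")
  if (length(grouping) == 0L) stop("empty grouping")
  grouped <- names(loadings) %in% names(grouping)
  n_ungrouped <- sum(!grouped)
  loadings <- loadings[grouped]
  grp <- unname(grouping[names(loadings)])
  pick <- if (sign == "positive") loadings > 0 else loadings < 0
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    vals <- loadings[grp == g & pick]
    data.frame(group = g,
               mean_loading = if (length(vals)) mean(vals) else NA_real_,
               n_sign = length(vals))
  }))
  attr(out, "n_ungrouped") <- n_ungrouped
  out
}

#' Full-data refit and encoding patterns for contributing channels
#'
#' After Monte Carlo evaluation, channels whose median meta-coefficient
#' interval excludes zero (the non-redundant contributors) are refit on the
#' entire set of observations with a fresh inner-CV penalty choice, and
#' their weight maps are transformed to max-abs-rescaled encoding patterns.
#' Screened-out channels get no map.
#'
#' @param channels List of [feature_channel()] objects.
#' @param y Response vector over all subjects (residualize beforehand if an
#'   imaging confounder is to be removed; see [residualize_response()]).
#' @param report A [evaluate_study()] `performance_report` used for channel
#'   screening.
#' @param inner_folds,seed Passed to the full-data [fit_lasso_pcr()].
#' @return Object of class `refit_result`: `patterns` (named list with
#'   `model`, `pattern`, `pattern_rescaled` per surviving channel) and
#'   `non_contributing` (channel names screened out).
#' @export
refit_full <- function(channels, y, report, inner_folds = 5L, seed = NULL) {
  channels <- as_channel_list(channels)
  stopifnot(inherits(report, "performance_report"))
  ss <- report$summary
  betas <- ss[ss$quantity == "meta_coefficient", ]
  surviving <- betas$model[betas$lower > 0 | betas$upper < 0]
  surviving <- intersect(names(channels), surviving)
  dropped <- setdiff(names(channels), surviving)
  if (length(surviving) == 0L)
    message("no channel's meta-coefficient interval excludes zero; ",
            "no maps emitted")
  patterns <- list()
  for (nm in surviving) {
    ch <- drop_zero_variance(channels[[nm]])$channel
    fit <- fit_lasso_pcr(ch$matrix, y, inner_folds = inner_folds,
                         seed = derive_seed(seed, paste0("refit_", nm)),
                         compute_oof = FALSE)
    pat <- encoding_pattern(fit$weight_map, ch$matrix, channel_name = nm)
    patterns[[nm]] <- list(model = fit, pattern = pat,
                           pattern_rescaled = maxabs_rescale(pat))
  }
  structure(list(patterns = patterns, non_contributing = dropped),
            class = "refit_result")
}
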