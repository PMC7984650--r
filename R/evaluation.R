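#' Family-respecting Monte Carlo train/test splits
#'
#' Generates repeated random 70/30-style partitions in which every family
#' group (e.g. a twin pair) falls wholly inside one side, preventing the
#' optimistic bias of related subjects straddling train and test. Groups
#' are shuffled and accumulated into the test side until its size is as
#' close as possible to `round(test_fraction * n)`; the achieved test size
#' is therefore always within one group size of the target. Optional
#' stratification allocates groups within bins of the group-mean response.
#'
#' @param n Number of subjects.
#' @param family_groups Vector of group labels, one per subject; singletons
#'   get their own label.
#' @param strata Optional per-subject numeric response used for
#'   stratification: group means are binned into `n_bins` quantile bins and
#'   groups are allocated within bins. Default `NULL` (plain group
#'   shuffling).
#' @param n_splits Number of random splits (default 100).
#' @param test_fraction Fraction of subjects in the test side (default 0.3).
#' @param seed Integer seed; split `s` is reproducible and unchanged by
#'   increasing `n_splits`.
#' @param n_bins Number of stratification bins (default 5).
#' @return Object of class `split_plan`: `splits` (list of
#'   `list(train, test)` integer index vectors) plus the settings.
#' @export
monte_carlo_splits <- function(n, family_groups, strata = NULL,
                               n_splits = 100L, test_fraction = 0.3,
                               seed = NULL, n_bins = 5L) {
  if (length(family_groups) != n) stop("family_groups must have length n")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  if (n_splits < 1L) stop("n_splits must be at least 1")
  groups <- as.character(family_groups)
  members <- split(seq_len(n), groups)
  sizes <- lengths(members)
  target <- round(test_fraction * n)
  if (max(sizes) > target)
    stop("a single family group (size ", max(sizes),
         ") exceeds the test-set size (", target, ")")

  bins <- rep(1L, length(members))
  if (!is.null(strata)) {
    if (length(strata) != n) stop("strata must have length n")
    gm <- vapply(members, function(ix) mean(as.numeric(strata[ix])), numeric(1))
    qs <- unique(stats::quantile(gm, probs = seq(0, 1, length.out = n_bins + 1L)))
    bins <- as.integer(cut(gm, qs, include.lowest = TRUE))
  }

  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    test_groups <- character(0)
    with_local_seed(derive_seed(seed, "split", s), {
      for (bn in unique(bins)) {
        in_bin <- which(bins == bn)
        perm <- in_bin[sample.int(length(in_bin))]
        bin_target <- test_fraction * sum(sizes[in_bin])
        size_cum <- cumsum(sizes[perm])
        m <- sum(size_cum < bin_target)
        if (m < length(perm) &&
            abs(size_cum[m + 1L] - bin_target) <
              abs((if (m == 0L) 0 else size_cum[m]) - bin_target))
          m <- m + 1L
        test_groups <- c(test_groups, names(sizes)[perm[seq_len(m)]])
      }
    })
    test_idx <- sort(unlist(members[test_groups], use.names = FALSE))
    splits[[s]] <- list(train = setdiff(seq_len(n), test_idx),
                        test = test_idx)
  }
  structure(list(splits = splits, n = n, test_fraction = test_fraction,
                 n_splits = n_splits, groups = groups, seed = seed,
                 stratified = !is.null(strata)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  ts <- vapply(x$splits, function(s) length(s$test), integer(1))
  cat("<split_plan> ", x$n_splits, " splits of ", x$n, " subjects, test sizes ",
      min(ts), "-", max(ts), "\n", sep = "")
  invisible(x)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, computed on the
#' evaluation set. Negative values mean the predictions do worse than the
#' evaluation-set mean.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return A single number, possibly negative.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0L) stop("empty vectors")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0) stop("zero-variance y_true: R^2 undefined")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Mean absolute error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return `mean(abs(y_true - y_pred))`.
#' @export
mean_absolute_error <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0L) stop("empty vectors")
  mean(abs(y_true - y_pred))
}

#' Stacking bonus
#'
#' The gain of the stacked model over its single-channel parts on one
#' split: either against the average single-channel performance
#' (`mode = "mean"`) or, more conservatively, against the best single
#' channel (`mode = "best"`, the default). Summarize per-split bonuses with
#' [bootstrap_median_ci()].
#'
#' @param r2_stacking Stacked model's out-of-sample R-squared.
#' @param r2_singles Numeric vector of single-channel R-squared values.
#' @param mode `"best"` or `"mean"`.
#' @return A single bonus value `B`.
#' @export
stacking_bonus <- function(r2_stacking, r2_singles, mode = c("best", "mean")) {
  mode <- match.arg(mode)
  if (length(r2_singles) == 0L) stop("empty r2_singles")
  r2_stacking - switch(mode, best = max(r2_singles), mean = mean(r2_singles))
}

#' Percentile-bootstrap confidence interval of the median
#'
#' Resamples `values` with replacement `n_boot` times, takes the median of
#' each resample and reports the `alpha/2` and `1 - alpha/2` percentiles.
#'
#' @param values Nonempty numeric vector (e.g. per-split metrics).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @param seed Integer seed for the resampling.
#' @return List with `median`, `lower`, `upper`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 1000L, alpha = 0.05,
                                seed = NULL) {
  if (length(values) == 0L) stop("empty values")
  meds <- with_local_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) stats::median(sample(values, replace = TRUE)),
           numeric(1))
  })
  ci <- unname(stats::quantile(meds, c(alpha / 2, 1 - alpha / 2)))
  list(median = stats::median(values), lower = ci[1L], upper = ci[2L])
}

#' Paired one-tailed comparison of two channels' per-split metrics
#'
#' Wilcoxon signed-rank test of the alternative "a exceeds b" on paired
#' per-split scores, with the matched-pairs rank-biserial correlation as
#' effect size: `(T+ - T-) / (T+ + T-)` over the ranks of the nonzero
#' absolute differences. Zero differences are discarded (standard signed-
#' rank convention); if all differences are zero the test is degenerate and
#' reported as `p = 1` with a warning.
#'
#' @param scores_a,scores_b Paired numeric vectors (length >= 5).
#' @return List with `p_value`, `rank_biserial`, `degenerate`.
#' @export
compare_channels <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stop("paired vectors required")
  if (length(scores_a) < 5L) stop("need at least 5 pairs")
  d <- scores_a - scores_b
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    warning("all paired differences are zero; comparison is degenerate")
    return(list(p_value = 1, rank_biserial = 0, degenerate = TRUE))
  }
  r <- rank(abs(nz))
  t_pos <- sum(r[nz > 0]); t_neg <- sum(r[nz < 0])
  wt <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, paired = TRUE,
                       alternative = "greater"))
  list(p_value = unname(wt$p.value),
       rank_biserial = (t_pos - t_neg) / (t_pos + t_neg),
       degenerate = FALSE)
}

#' Monte Carlo evaluation of the two-level pipeline
#'
#' The full performance protocol: repeated family-respecting train/test
#' splits, a complete [run_two_level()] fit per split, per-split R-squared
#' and mean absolute error for every channel and for the stacked model,
#' per-split channel meta-coefficients and stacking bonuses, and
#' percentile-bootstrap confidence intervals of the medians.
#'
#' @inheritParams run_two_level
#' @param family_groups Group labels (twins share one), length of the
#'   cohort.
#' @param n_splits,test_fraction,strata Passed to [monte_carlo_splits()].
#' @param n_boot,alpha Bootstrap settings for the summary intervals.
#' @param seed Master seed; splits, fold assignments and bootstraps all
#'   derive from it.
#' @return Object of class `performance_report`: `per_split` (split, model,
#'   r2, mae), `meta_coefficients` (split, channel, beta), `bonus` (split,
#'   b_best, b_mean) and `summary` (quantity, model, median, lower, upper).
#' @export
evaluate_study <- function(channels, y, family_groups, icv = NULL,
                           n_splits = 100L, test_fraction = 0.3,
                           inner_folds = 5L, strata = NULL,
                           n_boot = 1000L, alpha = 0.05, seed = NULL) {
  channels <- as_channel_list(channels)
  n <- length(y)
  plan <- monte_carlo_splits(n, family_groups, strata = strata,
                             n_splits = n_splits,
                             test_fraction = test_fraction,
                             seed = derive_seed(seed, "splits"))
  ch_names <- names(channels)
  per_split <- list(); coefs <- list(); bonus <- list()
  for (s in seq_len(n_splits)) {
    sp <- plan$splits[[s]]
    fit <- run_two_level(channels, y, sp$train, sp$test, icv = icv,
                         inner_folds = inner_folds,
                         seed = derive_seed(seed, "fit", s))
    r2_single <- vapply(ch_names, function(nm)
      r_squared(fit$y_test, fit$channel_test_predictions[, nm]), numeric(1))
    mae_single <- vapply(ch_names, function(nm)
      mean_absolute_error(fit$y_test, fit$channel_test_predictions[, nm]),
      numeric(1))
    r2_stack <- r_squared(fit$y_test, fit$stacked_test_predictions)
    per_split[[s]] <- data.frame(
      split = s, model = c(ch_names, "stacked"),
      r2 = c(r2_single, r2_stack),
      mae = c(mae_single,
              mean_absolute_error(fit$y_test, fit$stacked_test_predictions)),
      row.names = NULL)
    coefs[[s]] <- data.frame(split = s, channel = ch_names,
                             beta = unname(fit$stacked_model$coefficients[ch_names]),
                             row.names = NULL)
    bonus[[s]] <- data.frame(
      split = s,
      b_best = stacking_bonus(r2_stack, r2_single, "best"),
      b_mean = stacking_bonus(r2_stack, r2_single, "mean"))
  }
  per_split <- do.call(rbind, per_split)
  coefs <- do.call(rbind, coefs)
  bonus <- do.call(rbind, bonus)

  summ <- list()
  for (m in c(ch_names, "stacked")) {
    ci <- bootstrap_median_ci(per_split$r2[per_split$model == m],
                              n_boot, alpha, derive_seed(seed, paste0("boot_r2_", m)))
    summ[[length(summ) + 1L]] <- data.frame(quantity = "r2", model = m,
                                            median = ci$median, lower = ci$lower,
                                            upper = ci$upper)
  }
  for (m in ch_names) {
    ci <- bootstrap_median_ci(coefs$beta[coefs$channel == m],
                              n_boot, alpha, derive_seed(seed, paste0("boot_beta_", m)))
    summ[[length(summ) + 1L]] <- data.frame(quantity = "meta_coefficient",
                                            model = m, median = ci$median,
                                            lower = ci$lower, upper = ci$upper)
  }
  for (bm in c("b_best", "b_mean")) {
    ci <- bootstrap_median_ci(bonus[[bm]], n_boot, alpha,
                              derive_seed(seed, paste0("boot_", bm)))
    summ[[length(summ) + 1L]] <- data.frame(quantity = bm, model = "stacked",
                                            median = ci$median, lower = ci$lower,
                                            upper = ci$upper)
  }
  structure(
    list(per_split = per_split, meta_coefficients = coefs, bonus = bonus,
         summary = do.call(rbind, summ), plan = plan,
         settings = list(n_splits = n_splits, test_fraction = test_fraction,
                         inner_folds = inner_folds, n_boot = n_boot,
                         alpha = alpha, seed = seed)),
    class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report> ", x$settings$n_splits, " splits\n", sep = "")
  print(transform(x$summary, median = round(median, 4),
                  lower = round(lower, 4), upper = round(upper, 4)),
        row.names = FALSE)
  invisible(x)
}
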