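test_that("families never straddle a split and test sizes hit the target", {
  set.seed(40)
  n <- 200
  fams <- c(rep(sprintf("t%02d", 1:50), each = 2), sprintf("s%02d", 1:100))
  plan <- monte_carlo_splits(n, fams, n_splits = 25, seed = 7)
  target <- round(0.3 * n)
  for (sp in plan$splits) {
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), 1:n)
    # every family wholly on one side
    side <- tapply(seq_len(n) %in% sp$test, fams, function(z)
      length(unique(z)))
    expect_true(all(side == 1))
    expect_lte(abs(length(sp$test) - target), 2L)  # max family size
  }
  # determinism, and earlier splits unchanged by asking for more
  plan2 <- monte_carlo_splits(n, fams, n_splits = 30, seed = 7)
  expect_identical(plan$splits, plan2$splits[1:25])
})

test_that("small-cohort splits allocate whole families only", {
  fams <- rep(letters[1:5], each = 2)  # 10 subjects, 5 families of 2
  plan <- monte_carlo_splits(10, fams, n_splits = 20, test_fraction = 0.3,
                             seed = 1)
  sizes <- sapply(plan$splits, function(sp) length(sp$test))
  expect_true(all(sizes %in% c(2L, 4L)))  # 1 or 2 whole families
  expect_error(monte_carlo_splits(10, rep("one", 10), test_fraction = 0.3),
               "exceeds the test-set size")
})

test_that("stratified splits balance the response across sides", {
  set.seed(41)
  n <- 300
  y <- sort(rnorm(n))  # extreme ordering: stratification must mix it
  fams <- sprintf("s%03d", 1:n)
  plan <- monte_carlo_splits(n, fams, strata = y, n_splits = 10, seed = 3)
  for (sp in plan$splits)
    expect_lt(abs(mean(y[sp$test]) - mean(y[sp$train])), 0.35)
})

test_that("metrics match hand-computed values", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(0, 0, 0)), 1 - 5 / 2)
  expect_error(r_squared(rep(1, 3), rnorm(3)), "zero-variance")
  expect_error(r_squared(1:3, 1:4), "mismatch")

  expect_equal(mean_absolute_error(c(1, 3), c(2, 2)), 1)
  expect_equal(mean_absolute_error(1:5, 1:5), 0)
  set.seed(1); a <- rnorm(6); b <- rnorm(6); perm <- sample(6)
  expect_equal(mean_absolute_error(a[perm], b[perm]),
               mean_absolute_error(a, b))
})

test_that("stacking bonus compares against mean or best single channel", {
  singles <- c(0.1, 0.2, 0.0, -0.1, 0.05)
  expect_equal(stacking_bonus(0.25, singles, "mean"), 0.20)
  expect_equal(stacking_bonus(0.25, singles, "best"), 0.05)
  expect_equal(stacking_bonus(max(singles), singles, "best"), 0)
  expect_error(stacking_bonus(0.1, numeric(0)), "empty")
  for (i in 1:20) {
    set.seed(i)
    s <- rnorm(5); st <- rnorm(1)
    expect_lte(stacking_bonus(st, s, "best"), stacking_bonus(st, s, "mean"))
  }
})

test_that("bootstrap median interval brackets the median deterministically", {
  ci <- bootstrap_median_ci(rep(3.5, 10), seed = 1)
  expect_equal(ci, list(median = 3.5, lower = 3.5, upper = 3.5))
  set.seed(42); v <- rnorm(40)
  c1 <- bootstrap_median_ci(v, seed = 9)
  c2 <- bootstrap_median_ci(v, seed = 9)
  expect_identical(c1, c2)
  expect_lte(c1$lower, c1$median)
  expect_lte(c1$median, c1$upper)
  expect_error(bootstrap_median_ci(numeric(0)), "empty")
})

test_that("channel comparison handles direction, ties and degeneracy", {
  a <- c(5, 6, 7, 8, 9, 10); b <- a - c(1, 2, 3, 4, 5, 6)
  res <- compare_channels(a, b)
  expect_equal(res$rank_biserial, 1)  # strictly greater elementwise
  expect_lt(res$p_value, 0.05)

  expect_warning(deg <- compare_channels(a, a), "degenerate")
  expect_equal(deg$p_value, 1)
  expect_equal(deg$rank_biserial, 0)
  expect_error(compare_channels(1:4, 2:5), "at least 5")
})

test_that("Monte Carlo evaluation produces a coherent report", {
  coh <- tiny_cohort(n = 90, dims = c(20, 10), shared = 0.4, seed = 50)
  rep <- evaluate_study(coh$channels, coh$response,
                        coh$metadata$family_group,
                        n_splits = 4, n_boot = 200, seed = 6)
  expect_s3_class(rep, "performance_report")
  expect_equal(nrow(rep$per_split), 4 * 3)  # 2 channels + stacked
  expect_equal(nrow(rep$bonus), 4)
  # medians recomputable from per-split values
  for (m in unique(rep$per_split$model)) {
    expect_equal(rep$summary$median[rep$summary$quantity == "r2" &
                                      rep$summary$model == m],
                 median(rep$per_split$r2[rep$per_split$model == m]))
  }
  expect_true(all(rep$summary$lower <= rep$summary$median + 1e-12))
  expect_true(all(rep$summary$median <= rep$summary$upper + 1e-12))
  # determinism of the whole protocol
  rep2 <- evaluate_study(coh$channels, coh$response,
                         coh$metadata$family_group,
                         n_splits = 4, n_boot = 200, seed = 6)
  expect_identical(rep$summary, rep2$summary)
})
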