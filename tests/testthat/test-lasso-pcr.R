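test_that("closed-form score LASSO agrees with an independent solver", {
  set.seed(10)
  n <- 60; p <- 25
  x <- matrix(rnorm(n * p), n, p)
  y <- x[, 1] - 2 * x[, 2] + rnorm(n)
  fit <- fit_lasso_pcr(x, y, seed = 1)
  b <- stackpcr:::pcr_basis(x)
  # our objective (1/n)||.||^2 + lam||.||_1 equals glmnet at lambda = lam/2
  g <- glmnet::glmnet(b$z, y - mean(y), lambda = fit$lambda / 2,
                      standardize = FALSE, intercept = FALSE, thresh = 1e-14)
  expect_equal(unname(fit$beta), as.numeric(g$beta), tolerance = 1e-8)
})

test_that("weight-map and score-space predictions coincide; axes orthonormal", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:40, 1); p <- sample(3:60, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- fit_lasso_pcr(x, y, seed = seed, inner_folds = 3)
    expect_lt(max(abs(crossprod(fit$v) - diag(ncol(fit$v)))), 1e-8)
    b <- stackpcr:::pcr_basis(x)
    via_w <- predict(fit, x)
    via_z <- drop(b$z %*% fit$beta) + fit$intercept
    expect_lt(max(abs(via_w - via_z)), 1e-8)
  }
})

test_that("vanishing penalty recovers the least-squares solution", {
  set.seed(4)
  x <- matrix(rnorm(30 * 6), 30, 6)
  y <- rnorm(30)
  fit <- fit_lasso_pcr(x, y, lambda_grid = 0, inner_folds = 0,
                       compute_oof = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  w_ols <- solve(crossprod(xc), crossprod(xc, y - mean(y)))
  expect_equal(unname(fit$weight_map), drop(w_ols), tolerance = 1e-6)
})

test_that("full shrinkage zeroes the map and predicts the training mean", {
  set.seed(5)
  x <- matrix(rnorm(40), 10, 4); y <- rnorm(10)
  b <- stackpcr:::pcr_basis(x)
  lam_max <- 2 * max(abs(crossprod(b$z, y - mean(y)))) / 10
  fit <- fit_lasso_pcr(x, y, lambda_grid = lam_max * 1.01, inner_folds = 0,
                       compute_oof = FALSE)
  expect_true(all(fit$beta == 0))
  expect_true(all(fit$weight_map == 0))
  expect_equal(unname(predict(fit, x)), rep(mean(y), 10))

  # rows equal to the column means predict the intercept
  fit2 <- fit_lasso_pcr(x, y, seed = 2, inner_folds = 3)
  at_mean <- matrix(fit2$column_means, 3, 4, byrow = TRUE)
  expect_equal(unname(predict(fit2, at_mean)), rep(fit2$intercept, 3))
})

test_that("sparsity is monotone along the penalty grid", {
  set.seed(6)
  x <- matrix(rnorm(50 * 20), 50, 20); y <- rnorm(50)
  b <- stackpcr:::pcr_basis(x)
  cvec <- drop(crossprod(b$z, y - mean(y)))
  grid <- exp(seq(log(2 * max(abs(cvec)) / 50), log(1e-4), length.out = 25))
  nnz <- sapply(grid, function(l)
    sum(stackpcr:::soft_threshold_scores(cvec, b$d2, l, 50) != 0))
  expect_true(all(diff(nnz) >= 0))  # grid decreasing => nnz non-decreasing
})

test_that("row duplication leaves the fit unchanged", {
  set.seed(7)
  x <- matrix(rnorm(20 * 8), 20, 8); y <- rnorm(20)
  lam <- 0.05
  f1 <- fit_lasso_pcr(x, y, lambda_grid = lam, inner_folds = 0,
                      compute_oof = FALSE)
  f2 <- fit_lasso_pcr(rbind(x, x), c(y, y), lambda_grid = lam,
                      inner_folds = 0, compute_oof = FALSE)
  expect_equal(f2$weight_map, f1$weight_map, tolerance = 1e-10)
  expect_equal(f2$intercept, f1$intercept)
})

test_that("out-of-fold predictions cover every row and respect the seed", {
  set.seed(8)
  x <- matrix(rnorm(30 * 5), 30, 5); y <- rnorm(30)
  p1 <- out_of_fold_predictions(x, y, k = 5, seed = 42)
  p2 <- out_of_fold_predictions(x, y, k = 5, seed = 42)
  p3 <- out_of_fold_predictions(x, y, k = 5, seed = 43)
  expect_length(p1, 30L)
  expect_false(anyNA(p1))
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_error(out_of_fold_predictions(x, y, k = 31), "more folds")
})

test_that("leave-one-out at zero penalty equals an explicit OLS loop", {
  set.seed(9)
  x <- matrix(rnorm(6 * 2), 6, 2); y <- rnorm(6)
  oof <- out_of_fold_predictions(x, y, k = 6, lambda_grid = 0, seed = 1)
  loo <- sapply(1:6, function(i) {
    d <- data.frame(y = y[-i], x[-i, , drop = FALSE])
    unname(predict(lm(y ~ ., d), data.frame(x[i, , drop = FALSE])))
  })
  expect_equal(oof, loo, tolerance = 1e-8)
})

test_that("weight map recovers the generative support above chance", {
  coh <- generate_cohort(simulation_config(
    n_subjects = 500, channel_dims = 1000, shared_loading_fraction = 0.5,
    unique_loading_fraction = 0, twin_fraction = 0, seed = 77))
  fit <- fit_lasso_pcr(coh$channels[[1]]$matrix, coh$response, seed = 3,
                       compute_oof = FALSE)
  support <- which(coh$truth$shared_loadings[[1]] != 0)
  top <- order(abs(fit$weight_map), decreasing = TRUE)[seq_len(100)]
  obs <- length(intersect(top, support))
  set.seed(11)
  null <- replicate(999, length(intersect(sample(1000, 100), support)))
  p_perm <- (1 + sum(null >= obs)) / 1000
  expect_lt(p_perm, 0.05)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_lasso_pcr(x, c(rnorm(9), NA)), "non-finite")
  expect_error(fit_lasso_pcr(x, rnorm(10), lambda_grid = numeric(0)), "empty")
  expect_error(fit_lasso_pcr(x, rnorm(10), lambda_grid = -1), "negative")
  fit <- fit_lasso_pcr(x, rnorm(10), seed = 1, inner_folds = 3)
  expect_error(predict(fit, matrix(0, 2, 5)), "columns")
})
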