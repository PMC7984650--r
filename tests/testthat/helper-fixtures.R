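# Small fixtures built in code; all randomness locally seeded.

random_symmetric <- function(p, seed = 1, zero_diag = TRUE) {
  set.seed(seed)
  m <- matrix(rnorm(p * p), p, p)
  m <- (m + t(m)) / 2
  if (zero_diag) diag(m) <- 0
  m
}

# A matrix with an exact prescribed sample covariance: whiten a random
# centered matrix, then color by the Cholesky factor of `sigma`.
matrix_with_covariance <- function(n, sigma, seed = 1) {
  p <- nrow(sigma)
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p)
  mc <- sweep(m, 2, colMeans(m))
  white <- mc %*% solve(chol(cov(mc)))
  white %*% chol(sigma)
}

tiny_cohort <- function(n = 80, dims = c(30, 15), shared = 0.3, unique = 0.1,
                        seed = 1, ...) {
  generate_cohort(simulation_config(
    n_subjects = n, channel_dims = dims,
    shared_loading_fraction = shared, unique_loading_fraction = unique,
    seed = seed, ...))
}
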