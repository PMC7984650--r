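test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_subjects = 3), "at least 4")
  expect_error(simulation_config(channel_dims = c(10, 0)), ">= 1")
  expect_error(simulation_config(shared_loading_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(twin_fraction = -0.1), "\\[0, 1\\]")
  expect_error(simulation_config(noise_sd = 0), "positive")
  expect_error(simulation_config(channel_dims = c(10, 10),
                                 shared_loading_fraction = 0.5,
                                 unique_loading_fraction = 0.3),
               "exceed 1")
})

test_that("the same seed regenerates the cohort bit-exactly", {
  cfg <- simulation_config(n_subjects = 40, channel_dims = c(12, 6), seed = 5)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  other <- generate_cohort(simulation_config(n_subjects = 40,
                                             channel_dims = c(12, 6),
                                             seed = 6))
  expect_false(identical(generate_cohort(cfg)$response, other$response))
})

test_that("twin structure matches the configured fraction", {
  coh <- generate_cohort(simulation_config(n_subjects = 100,
                                           channel_dims = 5,
                                           twin_fraction = 0.4, seed = 2))
  tab <- table(table(coh$metadata$family_group))  # brute-force size tally
  expect_equal(unname(tab["2"]), 20L)
  expect_equal(unname(tab["1"]), 60L)
  # truth loadings have channel dimensionality; shared ordering
  expect_length(coh$truth$shared_loadings[[1]], 5L)
  expect_equal(nrow(coh$channels[[1]]$matrix), length(coh$response))
})

test_that("twin traits correlate as configured", {
  coh <- generate_cohort(simulation_config(
    n_subjects = 1200, channel_dims = 2, twin_fraction = 1,
    twin_trait_correlation = 0.5, seed = 3))
  g <- coh$truth$shared_trait
  first <- seq(1, 1199, by = 2)
  expect_equal(cor(g[first], g[first + 1]), 0.5, tolerance = 0.1)
})

test_that("response variance decomposes into the configured shares", {
  cfg <- simulation_config(n_subjects = 4000, channel_dims = c(4, 4),
                           shared_loading_fraction = 0.3,
                           unique_loading_fraction = 0.15,
                           twin_fraction = 0, seed = 4)
  coh <- generate_cohort(cfg)
  shared_part <- coh$truth$shared_coef * coh$truth$shared_trait
  unique_part <- coh$truth$unique_latents %*% coh$truth$unique_coefs
  vy <- var(coh$response)
  expect_equal(var(shared_part) / vy, 0.3, tolerance = 0.05)
  expect_equal(var(drop(unique_part)) / vy, 0.3, tolerance = 0.05)
  expect_equal(vy, 1, tolerance = 0.1)
})

test_that("null loadings make the response independent of the channels", {
  coh <- generate_cohort(simulation_config(
    n_subjects = 120, channel_dims = 30, shared_loading_fraction = 0,
    unique_loading_fraction = 0, seed = 9))
  fit <- run_two_level(coh$channels, coh$response, 1:84, 85:120, seed = 1)
  expect_lt(r_squared(fit$y_test, fit$channel_test_predictions[, 1]), 0.1)
  # generative channel signal really is absent
  expect_lt(max(abs(cor(coh$channels[[1]]$matrix, coh$response))), 0.5)
})

test_that("confounder effects shift the response exactly as configured", {
  base_cfg <- simulation_config(n_subjects = 60, channel_dims = 8, seed = 12)
  base <- generate_cohort(base_cfg)

  cfg <- simulation_config(n_subjects = 60, channel_dims = 8, seed = 12,
                           confounder_effects = list(volume_response = 0.01))
  coh <- generate_cohort(cfg)
  v <- coh$metadata$intracranial_volume
  expect_equal(coh$response - base$response, 0.01 * (v - mean(v)))

  # all-zero effects leave the cohort unchanged
  replant <- plant_confounders(base, base_cfg)
  expect_identical(replant$response, base$response)
  expect_identical(replant$channels, base$channels)

  # volume -> feature slope reaches every column
  cfg2 <- simulation_config(n_subjects = 60, channel_dims = 8, seed = 12,
                            confounder_effects = list(volume_feature = 0.002))
  coh2 <- generate_cohort(cfg2)
  shift <- coh2$channels[[1]]$matrix - base$channels[[1]]$matrix
  expect_equal(shift, matrix(0.002 * (v - mean(v)), 60, 8,
                             dimnames = dimnames(shift)))
})

test_that("demographic-only signal is picked up by the confounder channel", {
  cfg <- simulation_config(
    n_subjects = 300, channel_dims = 20, shared_loading_fraction = 0,
    unique_loading_fraction = 0, seed = 21,
    confounder_effects = list(demographic = c(age = 0.15, sex = 1,
                                              education = 0.2)))
  coh <- generate_cohort(cfg)
  chans <- c(coh$channels, list(confounders = confounder_channel(coh$metadata)))
  fit <- run_two_level(chans, coh$response, 1:210, 211:300, seed = 2)
  r2 <- sapply(colnames(fit$channel_test_predictions), function(nm)
    r_squared(fit$y_test, fit$channel_test_predictions[, nm]))
  expect_gt(r2["confounders"], 0.3)
  expect_lt(r2["ch1"], 0.05)
})
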