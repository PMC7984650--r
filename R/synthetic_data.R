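#' Configuration for the synthetic multimodal cohort generator
#'
#' Describes a latent-trait generative model for a cohort with several
#' feature channels of (possibly very different) dimensionality. A shared
#' latent trait `g` and one unique latent `u_k` per channel drive both the
#' response and the channel matrices:
#'
#'   `y = a g + sum_k b_k u_k + confounders + sqrt(1 - a^2 - sum b_k^2) e`
#'
#'   `X_k = sqrt(s_k) g p_k' + b_k u_k q_k' + noise_sd E_k`
#'
#' with `g, u_k, e, E_k` standard normal and `p_k, q_k` sparse loading
#' vectors (`loading_sparsity` nonzero, values standard normal). The
#' response's shared-trait variance share is `a^2 = mean(s_k)` over
#' channels; channel `k`'s unique latent contributes variance share
#' `b_k^2 = unique_loading_fraction[k]`. Subjects in twin pairs share a
#' family id and have their traits `g` drawn from a bivariate normal with
#' correlation `twin_trait_correlation`.
#'
#' @param n_subjects Cohort size (at least 4).
#' @param channel_dims Integer vector of feature counts, one per channel.
#' @param shared_loading_fraction Per-channel fraction in `[0, 1]` of
#'   response variance carried by the shared trait as expressed in that
#'   channel (recycled across channels).
#' @param unique_loading_fraction Per-channel fraction in `[0, 1]` of
#'   response variance carried by that channel's unique latent (recycled).
#' @param noise_sd Standard deviation of the channel feature noise.
#' @param twin_fraction Fraction of subjects belonging to a twin pair.
#' @param twin_trait_correlation Correlation of twin pairs' shared traits.
#' @param confounder_effects List with `volume_response` (slope of centered
#'   intracranial volume on the response), `volume_feature` (slope of
#'   centered volume added to every feature column) and `demographic`
#'   (named numeric vector of slopes for centered `age`, `sex`, `education`
#'   on the response). All default to zero.
#' @param loading_sparsity Fraction of nonzero entries in the generative
#'   loading vectors (default 0.1).
#' @param seed Integer seed; the same configuration regenerates bit-exactly.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 400L,
                              channel_dims = c(200L, 100L, 50L),
                              shared_loading_fraction = 0.2,
                              unique_loading_fraction = 0.1,
                              noise_sd = 1,
                              twin_fraction = 0.4,
                              twin_trait_correlation = 0.5,
                              confounder_effects = list(),
                              loading_sparsity = 0.1,
                              seed = 1L) {
  k <- length(channel_dims)
  if (k < 1L || any(channel_dims < 1L)) stop("channel_dims must all be >= 1")
  if (n_subjects < 4L) stop("n_subjects must be at least 4")
  shared <- rep_len(shared_loading_fraction, k)
  unique_ <- rep_len(unique_loading_fraction, k)
  fracs <- c(shared, unique_, twin_fraction, twin_trait_correlation,
             loading_sparsity)
  if (any(fracs < 0 | fracs > 1))
    stop("all fractions and correlations must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (mean(shared) + sum(unique_) > 1)
    stop("variance shares exceed 1: mean(shared) + sum(unique) = ",
         round(mean(shared) + sum(unique_), 3))
  defaults <- list(volume_response = 0, volume_feature = 0,
                   demographic = c(age = 0, sex = 0, education = 0))
  ce <- utils::modifyList(defaults, confounder_effects)
  structure(
    list(n_subjects = as.integer(n_subjects),
         channel_dims = as.integer(channel_dims),
         shared_loading_fraction = shared,
         unique_loading_fraction = unique_,
         noise_sd = noise_sd,
         twin_fraction = twin_fraction,
         twin_trait_correlation = twin_trait_correlation,
         confounder_effects = ce,
         loading_sparsity = loading_sparsity,
         seed = as.integer(seed)),
    class = "simulation_config")
}

sparse_loadings <- function(p, sparsity) {
  nnz <- max(1L, round(sparsity * p))
  v <- numeric(p)
  v[sample.int(p, nnz)] <- stats::rnorm(nnz)
  v
}

#' Generate a synthetic multimodal cohort
#'
#' Draws a cohort from the latent model described in [simulation_config()]:
#' channels sharing one latent trait plus channel-unique components, twin
#' pairs with correlated traits, and (via [plant_confounders()], applied
#' internally) an intracranial-volume confounder and demographic mediators.
#' The generative loadings and latent values are returned as ground truth so
#' recovery can be tested.
#'
#' @param config A [simulation_config()].
#' @return Object of class `synthetic_cohort`: `channels` (list of
#'   [feature_channel()]), `response` (numeric vector), `metadata` (data
#'   frame with `subject_id`, `family_group`, `intracranial_volume`, `age`,
#'   `sex`, `education`), `truth` (latents and loadings) and `config`.
#' @export
#' @examples
#' coh <- generate_cohort(simulation_config(n_subjects = 50,
#'                                          channel_dims = c(20, 10)))
#' sapply(coh$channels, function(ch) dim(ch$matrix))
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, {
    n <- config$n_subjects
    k <- length(config$channel_dims)
    n_pairs <- round(config$twin_fraction * n / 2)

    # family structure: first 2*n_pairs subjects form twin pairs
    family <- character(n)
    if (n_pairs > 0)
      family[seq_len(2 * n_pairs)] <- rep(sprintf("fam%04d", seq_len(n_pairs)),
                                          each = 2L)
    singles <- which(family == "")
    family[singles] <- sprintf("fam%04d", n_pairs + seq_along(singles))

    # shared trait, twin-correlated within pairs
    rho <- config$twin_trait_correlation
    g <- stats::rnorm(n)
    if (n_pairs > 0) {
      first <- seq(1L, by = 2L, length.out = n_pairs)
      g[first + 1L] <- rho * g[first] + sqrt(1 - rho^2) * g[first + 1L]
    }

    u <- matrix(stats::rnorm(n * k), n, k)
    a <- sqrt(mean(config$shared_loading_fraction))
    b <- sqrt(config$unique_loading_fraction)
    resid_sd <- sqrt(max(0, 1 - a^2 - sum(b^2)))
    y <- a * g + drop(u %*% b) + resid_sd * stats::rnorm(n)

    channels <- vector("list", k)
    shared_loadings <- vector("list", k)
    unique_loadings <- vector("list", k)
    for (j in seq_len(k)) {
      p <- config$channel_dims[j]
      pj <- sparse_loadings(p, config$loading_sparsity)
      qj <- sparse_loadings(p, config$loading_sparsity)
      x <- sqrt(config$shared_loading_fraction[j]) * tcrossprod(g, pj) +
        b[j] * tcrossprod(u[, j], qj) +
        config$noise_sd * matrix(stats::rnorm(n * p), n, p)
      nm <- paste0("ch", j)
      channels[[j]] <- feature_channel(nm, x,
                                       feature_labels = paste0(nm, "_f", seq_len(p)))
      shared_loadings[[j]] <- pj
      unique_loadings[[j]] <- qj
    }
    names(channels) <- vapply(channels, function(ch) ch$name, character(1))

    meta <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      family_group = family,
      intracranial_volume = pmax(stats::rnorm(n, 1500, 150), 800),
      age = stats::runif(n, 22, 37),
      sex = sample(c("F", "M"), n, replace = TRUE),
      education = sample(11:21, n, replace = TRUE),
      stringsAsFactors = FALSE)

    cohort <- structure(
      list(channels = channels, response = y, metadata = meta,
           truth = list(shared_trait = g, unique_latents = u,
                        shared_loadings = shared_loadings,
                        unique_loadings = unique_loadings,
                        shared_coef = a, unique_coefs = b),
           config = config),
      class = "synthetic_cohort")
    plant_confounders(cohort, config)
  })
}

#' Add confounder effects to a synthetic cohort
#'
#' Adds the configured intracranial-volume effect to the response and
#' (scaled by `volume_feature`) to every feature column of every channel,
#' plus demographic effects on the response. All effects use mean-centered
#' confounder values, so a `volume_response` slope `s` shifts the response
#' by exactly `s * (v - mean(v))`. With all effects zero the cohort is
#' returned unchanged.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config The [simulation_config()] holding `confounder_effects`.
#' @return The cohort with confounder contributions added.
#' @export
plant_confounders <- function(cohort, config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ce <- config$confounder_effects
  meta <- cohort$metadata
  vc <- meta$intracranial_volume - mean(meta$intracranial_volume)

  if (ce$volume_response != 0)
    cohort$response <- cohort$response + ce$volume_response * vc
  if (ce$volume_feature != 0)
    cohort$channels <- lapply(cohort$channels, function(ch) {
      ch$matrix <- ch$matrix + ce$volume_feature * vc
      ch
    })
  dem <- ce$demographic
  if (any(dem != 0)) {
    codes <- cbind(age = meta$age,
                   sex = as.numeric(meta$sex == "M"),
                   education = as.numeric(meta$education))
    codes <- sweep(codes, 2L, colMeans(codes))
    for (v in names(dem))
      if (dem[[v]] != 0)
        cohort$response <- cohort$response + dem[[v]] * codes[, v]
  }
  cohort
}

#' Write a synthetic cohort to delimited text files
#'
#' One tab-separated table per channel (first column `subject_id`, then one
#' column per feature), plus `response.tsv`, `metadata.tsv` and a
#' `config.yaml` echo of the generating configuration. The layout is what
#' [load_study()] reads back.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$metadata$subject_id
  paths <- character(0)
  for (ch in cohort$channels) {
    p <- file.path(dir, paste0("channel_", ch$name, ".tsv"))
    utils::write.table(data.frame(subject_id = ids, ch$matrix,
                                  check.names = FALSE),
                       p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  rp <- file.path(dir, "response.tsv")
  utils::write.table(data.frame(subject_id = ids, score = cohort$response),
                     rp, sep = "\t", row.names = FALSE, quote = FALSE)
  mp <- file.path(dir, "metadata.tsv")
  utils::write.table(cohort$metadata, mp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cp <- file.path(dir, "config.yaml")
  cfg <- unclass(cohort$config)
  cfg$confounder_effects$demographic <- as.list(cfg$confounder_effects$demographic)
  yaml::write_yaml(cfg, cp)
  invisible(c(paths, rp, mp, cp))
}
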