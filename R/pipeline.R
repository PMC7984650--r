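#' Load a multimodal study from delimited files
#'
#' Reads channel tables, a response table and a metadata table, joins them
#' by subject id (never by row position), drops subjects missing from any
#' table or with missing response/confounder values (with a reported
#' count), and returns consistently ordered in-memory objects.
#'
#' The configuration is a named list (or path to a YAML file) with at
#' least: `channels` (named list of file paths), `response` (file path,
#' column `score` or `response_column`), `metadata` (file path). Every
#' table's first joining column must be `subject_id`.
#'
#' @param config Named list or YAML file path.
#' @return List with `channels` (list of [feature_channel()]), `response`
#'   (numeric vector), `metadata` (data frame), `n_dropped`.
#' @export
load_study <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$channels) || is.null(config$response) ||
      is.null(config$metadata))
    stop("config must name 'channels', 'response' and 'metadata' files")

  read_tab <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  check_numeric <- function(df, path) {
    for (j in setdiff(names(df), "subject_id")) {
      col <- df[[j]]
      if (!is.numeric(col)) {
        conv <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(conv) & !is.na(col))
        if (length(bad))
          stop("malformed numeric cell in ", path, ", row ", bad[1L],
               ", column '", j, "': '", col[bad[1L]], "'")
        df[[j]] <- conv
      }
      nas <- which(is.na(df[[j]]))
      if (length(nas))
        stop("missing numeric value in ", path, ", row ", nas[1L],
             ", column '", j, "'")
    }
    df
  }

  ch_paths <- config$channels
  if (is.null(names(ch_paths)))
    names(ch_paths) <- sub("\\.[^.]*$", "", basename(unlist(ch_paths)))
  raw <- lapply(ch_paths, function(p) check_numeric(read_tab(p), p))
  resp <- read_tab(config$response)
  meta <- read_tab(config$metadata)
  score_col <- config$response_column %||%
    setdiff(names(resp), "subject_id")[1L]

  # subjects usable everywhere: present in all tables, complete response
  # and confounders
  ids <- Reduce(intersect, c(lapply(raw, `[[`, "subject_id"),
                             list(resp$subject_id, meta$subject_id)))
  complete <- resp$subject_id[!is.na(resp[[score_col]])]
  conf_cols <- intersect(c("intracranial_volume", "age", "sex", "education"),
                         names(meta))
  complete_meta <- meta$subject_id[stats::complete.cases(meta[conf_cols])]
  keep <- intersect(intersect(ids, complete), complete_meta)
  n_total <- length(unique(unlist(c(lapply(raw, `[[`, "subject_id"),
                                    list(resp$subject_id, meta$subject_id)))))
  if (length(keep) == 0L) stop("no subject is present in every table")
  n_dropped <- n_total - length(keep)
  if (n_dropped > 0)
    message(n_dropped, " subject(s) discarded (missing from a table or ",
            "with missing response/confounder values)")
  keep <- sort(keep)

  channels <- lapply(names(raw), function(nm) {
    df <- raw[[nm]]
    df <- df[match(keep, df$subject_id), , drop = FALSE]
    m <- as.matrix(df[setdiff(names(df), "subject_id")])
    rownames(m) <- keep
    feature_channel(nm, m)
  })
  names(channels) <- names(raw)
  resp <- resp[match(keep, resp$subject_id), , drop = FALSE]
  meta <- meta[match(keep, meta$subject_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(channels = channels,
       response = stats::setNames(resp[[score_col]], keep),
       metadata = meta, n_dropped = n_dropped)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

#' Run the complete analysis pipeline from a configuration
#'
#' The end-to-end workflow: load the study (or accept an in-memory one),
#' optionally append the demographic confounder channel, run the
#' family-respecting Monte Carlo evaluation of the two-level model with
#' optional train-only intracranial-volume adjustment, summarize medians
#' with bootstrap intervals, optionally refit contributing channels on all
#' observations for encoding maps, and write every table plus a manifest to
#' the output directory. Re-running with the same configuration reproduces
#' all numbers exactly.
#'
#' Recognized configuration fields (beyond [load_study()]'s):
#' `n_splits` (default 100), `test_fraction` (0.3), `inner_folds` (5),
#' `confounders` (`"none"` or `"channel"`), `icv_adjust` (logical, default
#' `TRUE`), `stratify` (logical, default `FALSE`), `n_boot` (1000), `alpha`
#' (0.05), `seed`, `maps` (logical, default `FALSE`), `output_dir`.
#'
#' @param config Named list or YAML file path.
#' @param study Optional preloaded [load_study()] result (files in `config`
#'   are then ignored).
#' @return Invisibly, a list with the `performance_report`, the optional
#'   `refit_result` and the output paths.
#' @export
run_pipeline <- function(config, study = NULL) {
  config <- read_run_config(config)
  if (is.null(study)) study <- load_study(config)
  channels <- study$channels
  y <- unname(study$response)
  meta <- study$metadata

  confounders <- config$confounders %||% "none"
  if (confounders == "channel")
    channels <- c(channels, list(confounders = confounder_channel(meta)))
  icv <- NULL
  if (isTRUE(config$icv_adjust %||% TRUE)) {
    if (!"intracranial_volume" %in% names(meta))
      stop("icv_adjust requested but metadata lacks 'intracranial_volume'")
    icv <- meta$intracranial_volume
  }
  strata <- if (isTRUE(config$stratify)) y else NULL

  report <- evaluate_study(
    channels, y, family_groups = meta$family_group, icv = icv,
    n_splits = config$n_splits %||% 100L,
    test_fraction = config$test_fraction %||% 0.3,
    inner_folds = config$inner_folds %||% 5L,
    strata = strata,
    n_boot = config$n_boot %||% 1000L,
    alpha = config$alpha %||% 0.05,
    seed = config$seed %||% 1L)

  maps <- NULL
  if (isTRUE(config$maps)) {
    y_map <- y
    if (!is.null(icv)) {
      adj <- residualize_response(y, numeric(0), icv, numeric(0))
      y_map <- adj$y_train
    }
    maps <- refit_full(channels, y_map, report,
                       inner_folds = config$inner_folds %||% 5L,
                       seed = derive_seed(config$seed %||% 1L, "maps"))
  }

  paths <- character(0)
  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
      p
    }
    paths <- c(wt(report$per_split, "per_split_metrics.tsv"),
               wt(report$meta_coefficients, "meta_coefficients.tsv"),
               wt(report$bonus, "stacking_bonus.tsv"),
               wt(report$summary, "summary.tsv"))
    if (!is.null(maps)) {
      for (nm in names(maps$patterns)) {
        pat <- maps$patterns[[nm]]$pattern_rescaled
        paths <- c(paths, wt(data.frame(feature = pat$feature_labels,
                                        loading = pat$loadings),
                             paste0("encoding_", nm, ".tsv")))
      }
    }
    manifest <- list(config = config,
                     package_version = as.character(utils::packageVersion("stackpcr")),
                     n_subjects = length(y),
                     channels = names(channels),
                     n_dropped = study$n_dropped %||% 0L)
    mp <- file.path(out_dir, "manifest.yaml")
    yaml::write_yaml(manifest, mp)
    paths <- c(paths, mp)
  }
  invisible(list(report = report, maps = maps, paths = paths))
}
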