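#' Construct a feature channel
#'
#' A feature channel is one modality's subjects-by-features numeric matrix
#' together with a short name, feature labels and an optional grouping of
#' features into anatomical units (tracts, regions, networks). Channels in a
#' study must share subject ordering; alignment is the caller's contract and
#' is enforced where channels meet ([concatenate_channels()],
#' [run_two_level()]).
#'
#' @param name Short channel label, e.g. `"fc"` or `"thickness"`.
#' @param matrix Numeric matrix, subjects in rows, features in columns. No
#'   missing values are allowed.
#' @param feature_labels Character vector of column labels; defaults to the
#'   matrix's column names or `f1, f2, ...`.
#' @param feature_groups Optional named character vector mapping feature
#'   label to group label (e.g. tract name), used by
#'   [group_average_loadings()].
#' @return An object of class `feature_channel`.
#' @export
#' @examples
#' ch <- feature_channel("toy", matrix(rnorm(20), 5, 4))
#' dim(ch$matrix)
feature_channel <- function(name, matrix, feature_labels = NULL,
                            feature_groups = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("channel '", name, "': matrix must be a numeric matrix")
  if (anyNA(matrix) || !all(is.finite(matrix)))
    stop("channel '", name, "': missing or non-finite values")
  if (is.null(feature_labels))
    feature_labels <- colnames(matrix) %||% paste0("f", seq_len(ncol(matrix)))
  if (length(feature_labels) != ncol(matrix))
    stop("channel '", name, "': feature_labels length (",
         length(feature_labels), ") != column count (", ncol(matrix), ")")
  colnames(matrix) <- feature_labels
  structure(
    list(name = as.character(name), matrix = matrix,
         feature_labels = as.character(feature_labels),
         feature_groups = feature_groups),
    class = "feature_channel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_channel <- function(x, ...) {
  cat("<feature_channel> '", x$name, "': ", nrow(x$matrix), " subjects x ",
      ncol(x$matrix), " features\n", sep = "")
  invisible(x)
}

as_channel_list <- function(channels) {
  if (inherits(channels, "feature_channel")) channels <- list(channels)
  if (!all(vapply(channels, inherits, logical(1), "feature_channel")))
    stop("expected feature_channel objects")
  nm <- vapply(channels, function(ch) ch$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate channel names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  names(channels) <- nm
  channels
}

#' Concatenate feature channels column-wise
#'
#' Appends the feature matrices of several channels into one wide channel,
#' the baseline against which stacking is compared (a single model on all
#' features at once). Feature labels are prefixed with their channel name.
#'
#' @param channels List of [feature_channel()] objects with identical
#'   subject ordering (equal row counts required).
#' @param name Name for the combined channel.
#' @return A single `feature_channel` whose column count is the sum of the
#'   inputs' column counts.
#' @export
concatenate_channels <- function(channels, name = "concatenated") {
  channels <- as_channel_list(channels)
  if (length(channels) == 0L) stop("no channels to concatenate")
  nr <- vapply(channels, function(ch) nrow(ch$matrix), integer(1))
  if (length(unique(nr)) != 1L)
    stop("row-count mismatch across channels: ",
         paste(unique(nr), collapse = " vs "))
  if (length(channels) == 1L) return(channels[[1L]])
  mats <- lapply(channels, function(ch) ch$matrix)
  labels <- unlist(lapply(channels, function(ch)
    paste(ch$name, ch$feature_labels, sep = ".")), use.names = FALSE)
  feature_channel(name, do.call(cbind, mats), feature_labels = labels)
}

#' Assemble the confounder channel from subject metadata
#'
#' Demographic mediators (age, sex, education) are not regressed out of the
#' response; instead they form one more channel whose predictions compete
#' with the imaging channels in the level-2 model. If the confounders carry
#' most of the response variance the non-negative L1 meta-model shrinks the
#' imaging channels away, which is the diagnostic the design intends.
#'
#' @param meta Data frame with columns `age` (numeric), `sex` (two-level
#'   factor or character) and `education` (numeric/ordinal). Missing values
#'   are an error: subjects with incomplete confounders should be dropped
#'   upstream (see [load_study()]).
#' @return A `feature_channel` named `"confounders"` with age, a single sex
#'   indicator (reference level dropped) and education as numeric columns.
#' @export
confounder_channel <- function(meta) {
  need <- c("age", "sex", "education")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  sub <- meta[need]
  if (anyNA(sub)) stop("missing values in confounders; drop those subjects first")
  sex <- factor(meta$sex)
  if (nlevels(sex) > 2L) stop("sex must have at most two levels")
  # one-hot with the first level as reference: a single indicator column
  sex_ind <- as.numeric(sex == levels(sex)[min(2L, nlevels(sex))])
  m <- cbind(age = as.numeric(meta$age),
             sex = sex_ind,
             education = as.numeric(meta$education))
  feature_channel("confounders", m,
                  feature_labels = c("age", paste0("sex_", levels(sex)[min(2L, nlevels(sex))]),
                                     "education"))
}
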