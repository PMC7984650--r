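# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' `.Random.seed`, so package functions never disturb the user's random
#' stream. A `NULL` seed runs `expr` against the current stream.
#'
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a sub-seed for a named stage from a master seed,
# so that e.g. adding splits never changes earlier splits' results. Kept
# below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stage, index = 0L) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stage))) %% 10000L
  as.integer((as.double(seed) * 48271 + h * 7919 + index) %% 2147483647)
}

# Balanced fold assignment: n rows into k folds, sizes differing by at most
# one, order randomized under `seed`.
assign_folds <- function(n, k, seed = NULL) {
  if (k < 2L) stop("need at least 2 folds")
  if (k > n) stop("more folds (", k, ") than rows (", n, ")")
  with_local_seed(seed, sample(rep_len(seq_len(k), n)))
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite values in ", what)
  invisible(x)
}
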