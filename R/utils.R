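# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded package functions do not perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a per-stage RNG substream seed from a master seed
#'
#' A single user-facing seed is split into deterministic substreams so that
#' individual simulation stages can be regenerated independently. Kept below
#' 2^31 so the result is always a valid integer seed.
#' @noRd
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 30269) %% 2147483629)
}

assert_count <- function(x, name, min = 0) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

assert_prob <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  invisible(as.numeric(x))
}

assert_nonneg <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0)
    stop(sprintf("`%s` must be a single non-negative number", name), call. = FALSE)
  invisible(as.numeric(x))
}

#' Validate a square symmetric distance-like matrix
#' @noRd
assert_distance_matrix <- function(d, name = "dist", require_zero_diag = TRUE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop(sprintf("`%s` must be a square numeric matrix or a 'dist' object", name),
         call. = FALSE)
  if (anyNA(d) || any(!is.finite(d)))
    stop(sprintf("`%s` contains NA/NaN/Inf values", name), call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop(sprintf("`%s` is not symmetric", name), call. = FALSE)
  if (require_zero_diag && any(abs(diag(d)) > 1e-8))
    stop(sprintf("`%s` must have a zero diagonal", name), call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("x", seq_len(nrow(d)))
  }
  d
}
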