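# Internal helpers shared across modules.

#' Run an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's `.Random.seed`,
#' so package functions are deterministic given their `seed` argument without
#' disturbing the user's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic sub-seed from a master seed and a key
#'
#' Substreams (per ISA setting, per null-set size, per trial) get their own
#' seeds so that adding one component does not shift the draws of another.
#' A small multiplicative hash keeps the result a valid 32-bit seed.
#'
#' @param seed master integer seed.
#' @param ... character or numeric key components.
#' @noRd
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), paste, character(1), collapse = ":"),
               collapse = "|")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h %% 2147483629) + 1L
}

# Validate a genes-by-samples expression matrix: numeric, unique dimnames.
check_expression_matrix <- function(x, arg = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("`%s` must have gene row names and sample column names", arg),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1]
    stop(sprintf("duplicate gene identifier: '%s'", dup), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- colnames(x)[duplicated(colnames(x))][1]
    stop(sprintf("duplicate sample identifier: '%s'", dup), call. = FALSE)
  }
  if (anyNA(x)) stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  invisible(x)
}

# Row-wise z-score (mean 0, variance 1 with denominator n-1).
scale_rows <- function(x) {
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  (x - mu) / sdv
}

# Column-wise z-score.
scale_cols <- function(x) {
  t(scale_rows(t(x)))
}

row_vars <- function(x) {
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (ncol(x) - 1)
}
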