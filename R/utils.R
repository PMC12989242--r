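#' Round half away from zero
#'
#' Base R's `round()` rounds halves to even; published tables in this field
#' round halves up. Used wherever a proportion is compared to a printed
#' percentage.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic per-stage seed in [0, 2^31): global seed + stage name hashed.
derive_seed <- function(seed, stage) {
  h <- rlang::hash(paste0(seed, "::", stage))
  (strtoi(substr(h, 1, 7), base = 16L) + as.integer(seed)) %% 2147483647L
}

# Validate that a named numeric vector is a probability simplex.
check_simplex <- function(x, field) {
  if (length(x) == 0 || is.null(names(x)) || any(!nzchar(names(x)))) {
    abort(sprintf("`%s` must be a non-empty named numeric vector.", field))
  }
  if (any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must have entries in [0, 1].", field))
  }
  if (abs(sum(x) - 1) > 1e-9) {
    abort(sprintf("`%s` must sum to 1 (got %.12f).", field, sum(x)))
  }
  invisible(x)
}

check_probs <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must have entries in [0, 1].", field))
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative and finite.", field))
  }
  invisible(x)
}
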