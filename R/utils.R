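`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a validation error
#'
#' Internal helper so that user-input failures are signalled with a common
#' condition class (`myomech_validation_error`) that callers and the CLI can
#' trap distinctly from programming errors.
#'
#' @param ... message parts, pasted with `sprintf`-style formatting.
#' @noRd
abort_validation <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c("myomech_validation_error", "error")))
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation("`%s` must be a single finite number", name)
  if (positive && x <= 0) abort_validation("`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) abort_validation("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

#' Derive a reproducible child seed from a master seed
#'
#' Keeps derived seeds below 2^31 - 1 so they remain valid R integers.
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000 + index) %% .Machine$integer.max)
}

#' Weighted mean and SD with frequency weights
#' @noRd
weighted_moments <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  v <- if (sw > 1) sum(w * (x - m)^2) / (sw - 1) else 0
  list(mean = m, sd = sqrt(max(v, 0)))
}
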