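#' Construct or coerce a mixture-motility dataset
#'
#' A mixture dataset is a data.frame with one row per observation of actin
#' gliding velocity at a given mole fraction of the fast motor.  Columns:
#' `k` (mole fraction, in `[0,1]`), `velocity_um_s` (>= 0), and optionally
#' `uncertainty_um_s` (half-width of a 95% CI or an SD, um/s),
#' `uncertainty_kind` (`"ci95"` or `"sd"`) and `n` (replicate count >= 1).
#' Replicate-level data simply repeat `k` values with `n = 1`.
#'
#' @param x data.frame with at least `k` and `velocity_um_s`.
#' @param metadata optional named list (pair labels, temperature, provenance),
#'   stored as an attribute.
#' @return data.frame of class `mixture_dataset`.
#' @export
as_mixture_dataset <- function(x, metadata = NULL) {
  if (inherits(x, "mixture_dataset") && is.null(metadata)) return(x)
  if (!is.data.frame(x)) abort_validation("mixture dataset must be a data.frame")
  need <- c("k", "velocity_um_s")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort_validation("mixture dataset is missing column(s): %s",
                     paste(miss, collapse = ", "))
  if (nrow(x) < 1L) abort_validation("mixture dataset is empty")
  if (anyNA(x$k) || any(x$k < 0 | x$k > 1))
    abort_validation("column `k` must lie in [0, 1] with no NA")
  if (anyNA(x$velocity_um_s) || any(x$velocity_um_s < 0))
    abort_validation("column `velocity_um_s` must be >= 0 with no NA")
  if (!is.null(x$n) && any(x$n < 1))
    abort_validation("column `n` must be >= 1")
  if (!is.null(x$uncertainty_kind)) {
    bad <- !x$uncertainty_kind %in% c("ci95", "sd")
    if (any(bad & !is.na(x$uncertainty_kind)))
      abort_validation("`uncertainty_kind` must be 'ci95' or 'sd'")
  }
  out <- x
  class(out) <- c("mixture_dataset", "data.frame")
  attr(out, "metadata") <- metadata %||% attr(x, "metadata")
  out
}

#' Aggregate replicate-level mixture observations per mole fraction
#'
#' Collapses repeated `k` values to one observation each, with the mean
#' velocity, the sample SD as `uncertainty_um_s` (`uncertainty_kind = "sd"`)
#' and the replicate count `n`.
#'
#' @param data a `mixture_dataset` or compatible data.frame.
#' @return aggregated `mixture_dataset` with unique `k`.
#' @export
aggregate_mixture_dataset <- function(data) {
  data <- as_mixture_dataset(data)
  sp <- split(data$velocity_um_s, data$k)
  out <- data.frame(
    k = as.numeric(names(sp)),
    velocity_um_s = vapply(sp, mean, numeric(1)),
    uncertainty_um_s = vapply(sp, function(v)
      if (length(v) > 1) stats::sd(v) else NA_real_, numeric(1)),
    uncertainty_kind = "sd",
    n = lengths(sp),
    row.names = NULL
  )
  as_mixture_dataset(out, metadata = attr(data, "metadata"))
}

#' Construct a gliding-speed sample
#'
#' Per-filament gliding speeds with nonnegative weights (conventionally the
#' number of frames each filament was tracked, so that long, well-tracked
#' filaments dominate the "weighted probability" of velocity).
#'
#' @param speeds numeric vector of filament speeds, um/s, >= 0.
#' @param weights nonnegative weights, recycled if scalar; not all zero.
#' @param label free-text condition label.
#' @param replicate optional factor/vector assigning each filament to a
#'   biological replicate (used for CIs and group comparisons).
#' @return object of class `speed_sample`.
#' @export
speed_sample <- function(speeds, weights = 1, label = "",
                         replicate = NULL) {
  if (!is.numeric(speeds) || length(speeds) < 1L || anyNA(speeds))
    abort_validation("`speeds` must be non-empty numeric without NA")
  if (any(speeds < 0)) abort_validation("speeds must be >= 0")
  weights <- rep_len(as.numeric(weights), length(speeds))
  if (anyNA(weights) || any(weights < 0))
    abort_validation("weights must be >= 0")
  if (sum(weights) <= 0) abort_validation("weights must not all be zero")
  if (!is.null(replicate) && length(replicate) != length(speeds))
    abort_validation("`replicate` must have one entry per speed")
  structure(list(speeds = speeds, weights = weights, label = label,
                 replicate = replicate),
            class = "speed_sample")
}

#' @export
print.speed_sample <- function(x, ...) {
  cat(sprintf("<speed_sample> %s: %d filaments, mean %.3g um/s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$speeds),
              sum(x$weights * x$speeds) / sum(x$weights)))
  invisible(x)
}
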