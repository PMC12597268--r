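#' Construct a three-bead trap recording
#'
#' Holds the two trapped-bead position series of an actin dumbbell (nm),
#' uniformly sampled at `sampling_rate`.  Synthetic recordings additionally
#' carry the generator's ground-truth event table in `truth`.
#'
#' @param bead1,bead2 numeric position series, nm, equal length.
#' @param sampling_rate Hz, > 0.
#' @param atp ATP concentration, uM (metadata).
#' @param truth optional data.frame of ground-truth events
#'   (`start_s`, `trans_s`, `end_s`, `substep1_nm`, `substep2_nm`).
#' @param metadata free-form named list.
#' @return object of class `trap_recording`.
#' @export
trap_recording <- function(bead1, bead2, sampling_rate, atp = NA_real_,
                           truth = NULL, metadata = list()) {
  assert_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (!is.numeric(bead1) || !is.numeric(bead2) ||
      length(bead1) != length(bead2) || length(bead1) < 2L)
    abort_validation("bead series must be numeric, equal length >= 2")
  structure(list(bead1 = bead1, bead2 = bead2,
                 sampling_rate = sampling_rate, atp = atp,
                 truth = truth, metadata = metadata),
            class = "trap_recording")
}

#' @export
print.trap_recording <- function(x, ...) {
  cat(sprintf("<trap_recording> %d samples at %g kHz (%.3g s)",
              length(x$bead1), x$sampling_rate / 1000,
              length(x$bead1) / x$sampling_rate))
  if (!is.null(x$truth)) cat(sprintf(", %d ground-truth events", nrow(x$truth)))
  cat("\n")
  invisible(x)
}

#' Mean bead position of a dumbbell recording
#'
#' The event position signal used downstream: the average of the two bead
#' series (symmetric dumbbell geometry).
#' @param rec a [trap_recording()].
#' @return numeric vector, nm.
#' @export
dumbbell_position <- function(rec) (rec$bead1 + rec$bead2) / 2

#' Construct an event set
#'
#' Ordered, non-overlapping actomyosin attachment intervals on the sample
#' clock of a recording.
#'
#' @param start_index,end_index integer sample indices (start < end).
#' @param sampling_rate Hz.
#' @param thresholds length-2 numeric `(low, high)` covariance thresholds
#'   used for detection, nm^2 (or NULL).
#' @param min_duration_s minimum duration enforced, s.
#' @return object of class `event_set`: data.frame with columns
#'   `start_index`, `end_index`, `duration_s` plus attributes.
#' @export
event_set <- function(start_index, end_index, sampling_rate,
                      thresholds = NULL, min_duration_s = 0) {
  if (length(start_index) != length(end_index))
    abort_validation("start/end index vectors must have equal length")
  if (length(start_index)) {
    if (any(end_index <= start_index))
      abort_validation("event end indices must exceed start indices")
    o <- order(start_index)
    start_index <- start_index[o]
    end_index <- end_index[o]
    if (any(start_index[-1] < end_index[-length(end_index)]))
      abort_validation("events overlap")
  }
  out <- data.frame(start_index = as.integer(start_index),
                    end_index = as.integer(end_index),
                    duration_s = (end_index - start_index) / sampling_rate)
  structure(out, class = c("event_set", "data.frame"),
            sampling_rate = sampling_rate, thresholds = thresholds,
            min_duration_s = min_duration_s)
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d events, mean duration %.3g s\n",
              nrow(x), if (nrow(x)) mean(x$duration_s) else NA))
  if (!is.null(attr(x, "thresholds")))
    cat(sprintf("  thresholds: low %.3g / high %.3g nm^2, min duration %.3g s\n",
                attr(x, "thresholds")[1], attr(x, "thresholds")[2],
                attr(x, "min_duration_s")))
  invisible(x)
}
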