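#' End-to-end analysis of one trap recording
#'
#' Runs the full single-molecule pipeline: windowed covariance, automatic
#' hysteresis thresholds, event detection, sample-resolution boundary
#' refinement, attachment-duration MLE, forward/reverse ensemble averages
#' with exponential rate fits, and per-event substep measurement.
#'
#' @param rec a [trap_recording()].
#' @param window_s covariance window, s (default 10 ms).
#' @param stride_s covariance stride, s (default `window_s / 4`).
#' @param min_duration_s minimum event duration, s (default 2 windows).
#' @param thresholds optional `(low, high)` nm^2; `NULL` uses
#'   [auto_thresholds()].
#' @param refine refine boundaries by changepoint (default TRUE).
#' @param forward_span_s,reverse_span_s ensemble spans, s.
#' @param guard_s ensemble-fit guard, s.
#' @param fit run the duration/ensemble fits (default TRUE); disable when the
#'   recording will be pooled with others via [pool_trap_analyses()].
#' @param ... passed to [measure_substeps()].
#' @return list of class `trap_analysis` with components `covariance`,
#'   `thresholds`, `events`, `duration_fit`, `forward`, `reverse`, `rates`,
#'   `substeps`, `n_events`.
#' @export
analyze_trap_recording <- function(rec, window_s = 0.010,
                                   stride_s = window_s / 4,
                                   min_duration_s = 2 * window_s,
                                   thresholds = NULL, refine = TRUE,
                                   forward_span_s = 0.15,
                                   reverse_span_s = 0.6,
                                   guard_s = 0.005, fit = TRUE, ...) {
  cov <- windowed_covariance(rec, window_s, stride_s)
  if (is.null(thresholds)) thresholds <- auto_thresholds(cov)
  ev <- detect_events(cov, thresholds[1], thresholds[2], min_duration_s)
  if (refine && nrow(ev)) ev <- refine_events(rec, ev)
  out <- list(covariance = cov, thresholds = thresholds, events = ev,
              n_events = nrow(ev), duration_fit = NULL, forward = NULL,
              reverse = NULL, rates = NULL, substeps = NULL)
  if (nrow(ev)) {
    out$forward <- ensemble_average(rec, ev, "forward", forward_span_s)
    out$reverse <- ensemble_average(rec, ev, "reverse", reverse_span_s)
    out$substeps <- measure_substeps(rec, ev, ...)
    if (fit) {
      out$duration_fit <- fit_exponential_rate(ev$duration_s, min_duration_s)
      out$rates <- fit_ensemble_rates(out$forward, out$reverse, guard_s)
    }
  }
  structure(out, class = "trap_analysis")
}

#' @export
print.trap_analysis <- function(x, ...) {
  cat(sprintf("<trap_analysis> %d events\n", x$n_events))
  if (!is.null(x$duration_fit))
    cat(sprintf("  k_detach (duration MLE): %.3g +/- %.2g s^-1\n",
                x$duration_fit$rate, x$duration_fit$stderr))
  if (!is.null(x$rates)) {
    cat(sprintf("  k1 (forward ensemble): %.4g s^-1 [%s]\n",
                x$rates$k1$rate, x$rates$k1$flag))
    cat(sprintf("  k2 (reverse ensemble): %.4g s^-1 [%s]\n",
                x$rates$k2$rate, x$rates$k2$flag))
  }
  if (!is.null(x$substeps)) {
    s <- attr(x$substeps, "summary")
    cat(sprintf("  substeps: %.3g nm + %.3g nm (n = %d)\n",
                s$mean_substep1, s$mean_substep2, s$n))
  }
  invisible(x)
}

#' Pool per-recording trap analyses and refit
#'
#' Concatenates event durations and substep tables, pools the forward and
#' reverse ensemble averages bin-wise, and refits the duration MLE and the
#' two ensemble rates on the pooled data.  Use this to reach a target event
#' count from several recordings (molecules) simulated or measured
#' separately.
#'
#' @param analyses list of [analyze_trap_recording()] results (with or
#'   without their own fits).
#' @param min_duration_s truncation point for the pooled duration MLE;
#'   defaults to the detection minimum of the first analysis.
#' @param guard_s ensemble-fit guard, s.
#' @return list of class `trap_analysis` (pooled; `covariance` is NULL).
#' @export
pool_trap_analyses <- function(analyses, min_duration_s = NULL,
                               guard_s = 0.005) {
  analyses <- Filter(function(a) a$n_events > 0, analyses)
  if (!length(analyses)) abort_validation("no events in any analysis")
  durations <- unlist(lapply(analyses, function(a) a$events$duration_s))
  if (is.null(min_duration_s))
    min_duration_s <- attr(analyses[[1]]$events, "min_duration_s") %||% 0
  fwd <- pool_ensemble_averages(lapply(analyses, `[[`, "forward"))
  rev <- pool_ensemble_averages(lapply(analyses, `[[`, "reverse"))
  substeps <- pool_substep_tables(lapply(analyses, `[[`, "substeps"))
  structure(list(
    covariance = NULL, thresholds = NULL, events = NULL,
    n_events = length(durations),
    duration_fit = fit_exponential_rate(durations, min_duration_s),
    forward = fwd, reverse = rev,
    rates = fit_ensemble_rates(fwd, rev, guard_s),
    substeps = substeps
  ), class = "trap_analysis")
}

#' Summarize a trap analysis as a flat list
#'
#' Convenience extractor used by the CLI and report writers.
#' @param x a `trap_analysis`.
#' @return named list of scalars.
#' @export
trap_analysis_summary <- function(x) {
  s <- if (!is.null(x$substeps)) attr(x$substeps, "summary") else NULL
  list(
    n_events = x$n_events,
    k_detach_per_s = if (!is.null(x$duration_fit)) x$duration_fit$rate else NA,
    k_detach_stderr = if (!is.null(x$duration_fit)) x$duration_fit$stderr else NA,
    k1_per_s = if (!is.null(x$rates)) x$rates$k1$rate else NA,
    k1_flag = if (!is.null(x$rates)) x$rates$k1$flag else NA,
    k2_per_s = if (!is.null(x$rates)) x$rates$k2$rate else NA,
    k2_flag = if (!is.null(x$rates)) x$rates$k2$flag else NA,
    substep1_nm = if (!is.null(s)) s$mean_substep1 else NA,
    substep2_nm = if (!is.null(s)) s$mean_substep2 else NA,
    total_step_nm = if (!is.null(s)) s$mean_total else NA
  )
}

#' Simulate and analyze trap recordings until an event target is reached
#'
#' Repeatedly simulates independent recordings (fresh molecules) with seeds
#' derived from `seed`, runs [analyze_trap_recording()] on each, and pools
#' them with [pool_trap_analyses()] once the pooled detected-event count
#' reaches `target_events`.  This mirrors how single-molecule datasets are
#' built in practice: many short recordings pooled to a target event count.
#'
#' @param seed master seed; recording `i` uses `seed * 1000 + i`.
#' @param target_events pooled event count to reach (default 516).
#' @param recording_s length of each simulated recording, s (default 120).
#' @param max_recordings safety cap (default 16).
#' @param params a [trap_sim_params()] whose `duration_s`/`seed` are
#'   overridden per recording; defaults to the standard generator settings.
#' @param guard_s ensemble-fit guard, s.
#' @return the pooled `trap_analysis` with an extra `n_recordings` element.
#' @export
trap_recovery_study <- function(seed, target_events = 516, recording_s = 120,
                                max_recordings = 16L,
                                params = trap_sim_params(),
                                guard_s = 0.005) {
  analyses <- list()
  n_pooled <- 0L
  i <- 0L
  while (n_pooled < target_events && i < max_recordings) {
    i <- i + 1L
    p_i <- params
    p_i$duration_s <- recording_s
    p_i$seed <- derive_seed(seed, i)
    an <- analyze_trap_recording(simulate_trap_recording(p_i),
                                 fit = FALSE, guard_s = guard_s)
    analyses[[i]] <- an
    n_pooled <- n_pooled + an$n_events
  }
  out <- pool_trap_analyses(analyses, guard_s = guard_s)
  out$n_recordings <- i
  out
}
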