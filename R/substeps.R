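#' Per-event two-substep displacement measurement
#'
#' For each event with a clean pre-event baseline, the substep-1 displacement
#' is the mean position over an early window at the start of the event minus
#' the baseline; the total displacement is the mean over a late window at the
#' end of the event minus the baseline; and substep 2 is total minus
#' substep 1 (so `total = substep1 + substep2` by construction).
#'
#' The early window is short (2 ms) because the substep-1 window competes
#' with the state-1 dwell itself: a window of width `w` overlaps the second
#' substep with probability `~k1 w`, inflating substep 1 by
#' `s2 (1 - (1 - exp(-k1 w))/(k1 w))`, which at the physiological state-1
#' rate is already ~0.07 nm at 2 ms and grows roughly linearly with `w`.
#' With refined boundaries (sub-millisecond start jitter) no start-side
#' guard is needed; the end keeps a small guard (`end_guard_s`) against
#' residual end jitter, which is cheap because the state-2 dwell is long.
#' Events shorter than
#' `start_guard + early_window + late_window + end_guard` are excluded from
#' the total/substep-2 columns (NA) and counted in `n_excluded`.
#'
#' @param rec a [trap_recording()].
#' @param events an [event_set()] (ideally refined; see [refine_events()]).
#' @param early_window_s substep-1 window, s (default 2 ms: long against the
#'   trap relaxation time, short against the state-1 dwell).
#' @param late_window_s total-displacement window, s (default 5 ms).
#' @param baseline_s,baseline_gap_s baseline window and gap, s.
#' @param start_guard_s gap between event start and the early window, s
#'   (default 0).
#' @param end_guard_s gap between the late window and the event end, s
#'   (default 1 ms).
#' @return object of class `substep_table`: data.frame with one row per
#'   usable event (`substep1_nm`, `substep2_nm`, `total_nm`, `duration_s`)
#'   and a `summary` attribute (means, SDs, `n`, `n_total`, `n_excluded`).
#' @export
measure_substeps <- function(rec, events, early_window_s = 0.002,
                             late_window_s = 0.005, baseline_s = 0.010,
                             baseline_gap_s = 0.005, start_guard_s = 0,
                             end_guard_s = 0.001) {
  if (!inherits(events, "event_set") || !nrow(events))
    abort_validation("`events` must be a non-empty event_set")
  p <- dumbbell_position(rec)
  fs <- rec$sampling_rate
  ne <- max(1L, round(early_window_s * fs))
  nl <- max(1L, round(late_window_s * fs))
  gs <- round(start_guard_s * fs)
  ge <- round(end_guard_s * fs)
  base <- event_baselines(p, events, fs, baseline_s, baseline_gap_s)
  rows <- list()
  n_excluded <- 0L
  for (j in seq_len(nrow(events))) {
    if (is.na(base[j])) next
    s <- events$start_index[j]
    e <- events$end_index[j]
    len <- e - s + 1L
    if (len < gs + ne) next                     # too short even for substep 1
    s1 <- mean(p[(s + gs):(s + gs + ne - 1L)]) - base[j]
    if (len >= gs + ne + nl + ge) {
      tot <- mean(p[(e - ge - nl + 1L):(e - ge)]) - base[j]
      s2 <- tot - s1
    } else {
      tot <- NA_real_
      s2 <- NA_real_
      n_excluded <- n_excluded + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      event = j, substep1_nm = s1, substep2_nm = s2, total_nm = tot,
      duration_s = events$duration_s[j])
  }
  if (!length(rows))
    abort_validation("no event qualifies for substep measurement")
  tab <- do.call(rbind, rows)
  ok2 <- !is.na(tab$substep2_nm)
  summary <- list(
    mean_substep1 = mean(tab$substep1_nm),
    sd_substep1 = stats::sd(tab$substep1_nm),
    mean_substep2 = mean(tab$substep2_nm[ok2]),
    sd_substep2 = stats::sd(tab$substep2_nm[ok2]),
    mean_total = mean(tab$total_nm[ok2]),
    sd_total = stats::sd(tab$total_nm[ok2]),
    n = nrow(tab), n_total = sum(ok2), n_excluded = n_excluded
  )
  structure(tab, class = c("substep_table", "data.frame"), summary = summary)
}

#' @export
print.substep_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<substep_table> %d events (%d with substep 2, %d too short)\n",
              s$n, s$n_total, s$n_excluded))
  cat(sprintf("  substep 1: %.3g +/- %.2g nm | substep 2: %.3g +/- %.2g nm | total: %.3g nm\n",
              s$mean_substep1, s$sd_substep1, s$mean_substep2, s$sd_substep2,
              s$mean_total))
  invisible(x)
}

#' Combine substep tables from several recordings
#'
#' @param tables list of [measure_substeps()] results.
#' @return a single `substep_table` with a recomputed summary.
#' @export
pool_substep_tables <- function(tables) {
  if (!length(tables)) abort_validation("no substep tables to pool")
  tab <- do.call(rbind, lapply(tables, as.data.frame))
  ok2 <- !is.na(tab$substep2_nm)
  summary <- list(
    mean_substep1 = mean(tab$substep1_nm),
    sd_substep1 = stats::sd(tab$substep1_nm),
    mean_substep2 = mean(tab$substep2_nm[ok2]),
    sd_substep2 = stats::sd(tab$substep2_nm[ok2]),
    mean_total = mean(tab$total_nm[ok2]),
    sd_total = stats::sd(tab$total_nm[ok2]),
    n = nrow(tab), n_total = sum(ok2),
    n_excluded = sum(vapply(tables, function(t)
      attr(t, "summary")$n_excluded, numeric(1)))
  )
  structure(tab, class = c("substep_table", "data.frame"), summary = summary)
}
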