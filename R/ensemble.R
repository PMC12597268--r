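# Per-event detached baseline: mean position over a window of `baseline_s`
# ending `gap_s` before the event start. Unusable (NA) when the window runs
# off the recording or into the previous event.
event_baselines <- function(p, events, fs, baseline_s = 0.010,
                            gap_s = 0.005) {
  nb <- round(baseline_s * fs)
  ng <- round(gap_s * fs)
  n_ev <- nrow(events)
  out <- rep(NA_real_, n_ev)
  prev_end <- c(0L, events$end_index[-n_ev])
  for (j in seq_len(n_ev)) {
    b1 <- events$start_index[j] - ng - 1L
    b0 <- b1 - nb + 1L
    if (b0 >= 1L && b0 > prev_end[j]) out[j] <- mean(p[b0:b1])
  }
  out
}

#' Event-aligned ensemble average of the power stroke
#'
#' Averages the baseline-subtracted mean bead position over many binding
#' events, aligned either at attachment (`mode = "forward"`, averaging
#' forward in time) or at detachment (`mode = "reverse"`, averaging backward
#' in time).  The forward average exposes the rise from the first to the
#' second substep level; the reverse average exposes the decay of occupancy
#' of the second state before detachment.
#'
#' Each event's baseline is the mean position over a `baseline_s` window
#' ending `baseline_gap_s` before its start; events without a clean baseline
#' window are skipped.  Events shorter than the span are, by default,
#' extended by holding their final (forward) or initial (reverse) attached
#' level, which keeps the per-bin event count constant and makes the
#' expected forward average exactly `s1 + s2 (1 - exp(-k1 t))`;
#' `extend = "drop"` instead leaves those bins to the surviving events.
#'
#' @param rec a [trap_recording()].
#' @param events an [event_set()] (ideally [refine_events()]-processed).
#' @param mode `"forward"` or `"reverse"`.
#' @param span_s length of the average, s.
#' @param baseline_s,baseline_gap_s baseline window and gap, s.
#' @param extend `"hold"` (default) or `"drop"`.
#' @param hold_window_s length of the window whose mean defines the held
#'   level for forward averages, s (default 8 ms; a longer window shrinks the
#'   per-event noise of the held constant, which otherwise accumulates as
#'   correlated noise in the plateau, and sits safely inside the long state-2
#'   dwell).  Reverse averages hold the initial attached level, which lives
#'   in the brief state-1 dwell, so their hold window is capped at 2 ms.
#' @param hold_guard_s gap between the event end and the forward hold window,
#'   s (default 1 ms; keeps residual end-jitter leakage of detached samples
#'   out of the held level).
#' @return object of class `ensemble_average`: list with `mode`, `times`
#'   (s; `>= 0` increasing for forward, `<= 0` increasing toward 0 for
#'   reverse), `mean_position` (nm), `n_events_per_bin`, `n_events`.
#' @export
ensemble_average <- function(rec, events, mode = c("forward", "reverse"),
                             span_s = 0.15, baseline_s = 0.010,
                             baseline_gap_s = 0.005,
                             extend = c("hold", "drop"),
                             hold_window_s = 0.008, hold_guard_s = 0.001) {
  mode <- match.arg(mode)
  extend <- match.arg(extend)
  if (!inherits(events, "event_set") || !nrow(events))
    abort_validation("`events` must be a non-empty event_set")
  assert_scalar_number(span_s, "span_s", positive = TRUE)
  p <- dumbbell_position(rec)
  fs <- rec$sampling_rate
  n <- length(p)
  m <- round(span_s * fs)
  nh <- max(1L, round(hold_window_s * fs))
  ng <- round(hold_guard_s * fs)
  base <- event_baselines(p, events, fs, baseline_s, baseline_gap_s)
  usable <- which(!is.na(base))
  if (!length(usable))
    abort_validation("no event has a usable pre-event baseline window")
  acc <- numeric(m)
  acc2 <- numeric(m)
  cnt <- numeric(m)
  for (j in usable) {
    s <- events$start_index[j]
    e <- events$end_index[j]
    if (mode == "forward") {
      idx <- s:min(e, s + m - 1L)
      vals <- p[idx] - base[j]
      k <- length(vals)
      if (k < m && extend == "hold") {
        h1 <- max(s, e - ng)
        hold <- mean(p[max(s, h1 - nh + 1L):h1]) - base[j]
        vals <- c(vals, rep(hold, m - k))
        k <- m
      }
      if (k < m) {                         # drop mode, short event
        acc[1:k] <- acc[1:k] + vals
        acc2[1:k] <- acc2[1:k] + vals^2
        cnt[1:k] <- cnt[1:k] + 1
        next
      }
    } else {
      idx <- max(s, e - m + 1L):e
      vals <- p[idx] - base[j]
      k <- length(vals)
      if (k < m) {
        if (extend == "hold") {
          # initial attached level: short window, the state-1 dwell is brief
          nh1 <- min(nh, max(1L, round(0.002 * fs)))
          hold <- mean(p[s:min(e, s + nh1 - 1L)]) - base[j]
          vals <- c(rep(hold, m - k), vals)
        } else {
          ok_i <- (m - k + 1L):m
          acc[ok_i] <- acc[ok_i] + vals
          acc2[ok_i] <- acc2[ok_i] + vals^2
          cnt[ok_i] <- cnt[ok_i] + 1
          next
        }
      }
    }
    acc <- acc + vals
    acc2 <- acc2 + vals^2
    cnt <- cnt + 1
  }
  times <- if (mode == "forward") (0:(m - 1L)) / fs else (-(m - 1L):0) / fs
  mp <- acc / pmax(cnt, 1)
  vv <- pmax(acc2 / pmax(cnt, 1) - mp^2, 0)
  structure(list(mode = mode, times = times,
                 mean_position = mp,
                 sd_position = sqrt(vv * cnt / pmax(cnt - 1, 1)),
                 n_events_per_bin = cnt, n_events = length(usable),
                 span_s = span_s, sampling_rate = fs,
                 sum_position = acc, sumsq_position = acc2),
            class = "ensemble_average")
}

#' @export
print.ensemble_average <- function(x, ...) {
  cat(sprintf("<ensemble_average> %s, %d events, span %.3g s, plateau %.3g nm\n",
              x$mode, x$n_events, x$span_s,
              mean(utils::tail(x$mean_position, 50))))
  invisible(x)
}

#' Pool ensemble averages across recordings
#'
#' Bin-wise weighted mean of several [ensemble_average()] objects computed
#' with the same mode, span and sampling rate (e.g. one per molecule or per
#' recording).
#'
#' @param averages list of `ensemble_average` objects.
#' @return a single `ensemble_average`.
#' @export
pool_ensemble_averages <- function(averages) {
  if (!length(averages)) abort_validation("no ensemble averages to pool")
  ref <- averages[[1]]
  for (a in averages) {
    if (!inherits(a, "ensemble_average"))
      abort_validation("all elements must be ensemble_average objects")
    if (a$mode != ref$mode || length(a$times) != length(ref$times) ||
        a$sampling_rate != ref$sampling_rate)
      abort_validation("ensemble averages are not commensurate")
  }
  acc <- numeric(length(ref$times))
  acc2 <- numeric(length(ref$times))
  cnt <- numeric(length(ref$times))
  for (a in averages) {
    acc <- acc + (a$sum_position %||% (a$mean_position * a$n_events_per_bin))
    acc2 <- acc2 + (a$sumsq_position %||% rep(NA_real_, length(acc2)))
    cnt <- cnt + a$n_events_per_bin
  }
  mp <- acc / pmax(cnt, 1)
  vv <- pmax(acc2 / pmax(cnt, 1) - mp^2, 0)
  structure(list(mode = ref$mode, times = ref$times,
                 mean_position = mp,
                 sd_position = sqrt(vv * cnt / pmax(cnt - 1, 1)),
                 n_events_per_bin = cnt,
                 n_events = sum(vapply(averages, `[[`, numeric(1), "n_events")),
                 span_s = ref$span_s, sampling_rate = ref$sampling_rate,
                 sum_position = acc, sumsq_position = acc2),
            class = "ensemble_average")
}

fit_single_exponential <- function(t, y, rising, n_points, weights = NULL) {
  # initialization from the 10-90% rise/decay of the smoothed curve
  y0 <- mean(utils::head(y, max(5L, length(y) %/% 50L)))
  y1 <- mean(utils::tail(y, max(5L, length(y) %/% 10L)))
  amp <- y1 - y0
  if (rising) {
    s1_0 <- y0; s2_0 <- amp
  } else {
    s1_0 <- y1; s2_0 <- y0 - y1
  }
  if (abs(s2_0) < 1e-6)
    return(rate_fit(NA_real_, NA_real_, n_points, "ensemble", "non-identifiable",
                    details = list(reason = "vanishing amplitude")))
  # fraction of the transition completed: 0 at the origin, 1 at the tail,
  # whichever direction the curve moves
  frac <- (y - y0) / amp
  t63 <- t[which(frac >= 0.632)[1]]
  k0 <- if (length(t63) && is.finite(t63) && t63 > t[1]) 1 / (t63 - t[1])
        else if (rising) 20 else 2
  k0 <- min(max(k0, 1e-2), 1e4)
  form <- if (rising) y ~ s1 + s2 * (1 - exp(-k * (t - t[1])))
          else y ~ s1 + s2 * exp(-k * (t - t[1]))
  if (is.null(weights)) weights <- rep(1, length(y))
  t0 <- t[1]
  model_y <- function(par) {
    if (rising) par[1] + par[2] * (1 - exp(-par[3] * (t - t0)))
    else par[1] + par[2] * exp(-par[3] * (t - t0))
  }
  wssr <- function(par) {
    if (par[2] < 0 || par[3] <= 0) return(Inf)
    sum(weights * (y - model_y(par))^2)
  }
  fit <- tryCatch(suppressWarnings(
    stats::nls(form, data = data.frame(t = t, y = y),
               start = list(s1 = s1_0, s2 = s2_0, k = k0),
               weights = weights,
               algorithm = "port",
               lower = c(s1 = -Inf, s2 = 1e-9, k = 1e-6),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) e)
  par <- if (inherits(fit, "error")) c(s1_0, abs(s2_0), k0)
         else unname(stats::coef(fit))
  # warnOnly-mode nls can return constraint-violating coefficients
  if (!is.finite(wssr(par))) par <- c(s1_0, max(abs(s2_0), 1e-6), k0)
  # polish (or rescue) with a derivative-free pass on the same objective;
  # nls "false convergence" on these flat weighted surfaces is routine
  op <- stats::optim(par, wssr, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  refit_ok <- FALSE
  if (op$value <= wssr(par) + 1e-12) {
    par <- op$par
    refit_ok <- op$convergence == 0
  }
  nls_ok <- !inherits(fit, "error") && isTRUE(fit$convInfo$isConv)
  if (!nls_ok && !refit_ok)
    return(rate_fit(NA_real_, NA_real_, n_points, "ensemble", "non-convergent",
                    details = list(reason = if (inherits(fit, "error"))
                      conditionMessage(fit) else fit$convInfo$stopMessage)))
  se <- if (nls_ok) tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                             error = function(e) NA_real_) else NA_real_
  rate_fit(par[3], se, n_points, "ensemble",
           details = list(s1 = par[1], s2 = par[2], t_origin = t0))
}

#' Fit the two-state rates to forward and reverse ensemble averages
#'
#' The forward average is fit to `s1 + s2 (1 - exp(-k1 t))` (the rise from
#' the substep-1 level toward the substep-2 plateau, rate = state-1 to
#' state-2 transition) and the reverse average to `s1 + s2 exp(-k2 |t|)`
#' (state-2 occupancy decaying toward the substep-1 level, rate = state-2 to
#' detachment).  Nonlinear least squares, initialized from the 10-90%
#' rise/decay times.  The first `guard_s` seconds next to the alignment point
#' are excluded: residual boundary jitter contaminates those bins, and a pure
#' time shift does not change either exponential rate, so the guard costs
#' only amplitude.  When the averages carry per-bin dispersions the fit is
#' weighted by the estimated variance of each bin mean
#' (`n_events_per_bin / sd^2`).  Non-convergent or amplitude-free fits are
#' returned flagged, never silently replaced.
#'
#' @param fwd,rev forward and reverse [ensemble_average()] objects.
#' @param guard_s time excluded next to the alignment point, s (default 5 ms).
#' @return list with elements `k1` and `k2`, both [rate_fit()] objects with
#'   models `"forward-ensemble"` and `"reverse-ensemble"`; `details` carries
#'   the fitted levels (`s1`, `s2`).
#' @export
fit_ensemble_rates <- function(fwd, rev, guard_s = 0.005) {
  if (!inherits(fwd, "ensemble_average") || fwd$mode != "forward")
    abort_validation("`fwd` must be a forward ensemble_average")
  if (!inherits(rev, "ensemble_average") || rev$mode != "reverse")
    abort_validation("`rev` must be a reverse ensemble_average")
  bin_weights <- function(ens, sel) {
    if (is.null(ens$sd_position)) return(NULL)
    sd <- ens$sd_position[sel]
    n <- ens$n_events_per_bin[sel]
    good <- is.finite(sd) & sd > 0
    if (!any(good)) return(NULL)
    sd[!good] <- stats::median(sd[good])
    w <- n / sd^2
    # held bins repeat one noisy constant per event, so their small apparent
    # variance overstates their information; cap the weights
    pmin(w, 3 * stats::median(w))
  }
  selF <- fwd$times >= guard_s
  f1 <- fit_single_exponential(fwd$times[selF], fwd$mean_position[selF],
                               rising = TRUE, n_points = fwd$n_events,
                               weights = bin_weights(fwd, selF))
  f1$model <- "forward-ensemble"
  u <- -rev$times
  selR <- u >= guard_s
  o <- order(u[selR])
  f2 <- fit_single_exponential(sort(u[selR]), rev$mean_position[selR][o],
                               rising = FALSE, n_points = rev$n_events,
                               weights = bin_weights(rev, selR)[o])
  f2$model <- "reverse-ensemble"
  list(k1 = f1, k2 = f2)
}
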