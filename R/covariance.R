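#' Sliding-window bead-bead covariance
#'
#' Sample covariance of the two mean-removed bead series in windows of
#' `window_s` seconds advanced by `stride_s`.  Actomyosin binding shows up as
#' a drop in this covariance: the correlated dumbbell fluctuation is damped
#' while the myosin holds the actin.  Timestamps are at window centers.
#'
#' @param rec a [trap_recording()].
#' @param window_s window length, s; must contain >= 10 samples.
#' @param stride_s window advance, s; `stride_s <= window_s`.
#' @return object of class `covariance_series`: list with `values` (nm^2),
#'   `times` (s, window centers), `center_index` (fractional sample index),
#'   `window_samples`, `stride_samples`, `sampling_rate`.
#' @export
windowed_covariance <- function(rec, window_s = 0.010,
                                stride_s = window_s / 4) {
  if (!inherits(rec, "trap_recording"))
    abort_validation("`rec` must be a trap_recording")
  fs <- rec$sampling_rate
  w <- round(window_s * fs)
  s <- max(1L, round(stride_s * fs))
  if (w < 10L)
    abort_validation("window must span >= 10 samples (got %d)", w)
  if (s > w) abort_validation("stride must not exceed the window")
  n <- length(rec$bead1)
  if (w > n) abort_validation("window longer than the recording")
  x <- rec$bead1
  y <- rec$bead2
  cx <- c(0, cumsum(x))
  cy <- c(0, cumsum(y))
  cxy <- c(0, cumsum(x * y))
  starts <- seq(1L, n - w + 1L, by = s)
  ends <- starts + w - 1L
  sx <- cx[ends + 1L] - cx[starts]
  sy <- cy[ends + 1L] - cy[starts]
  sxy <- cxy[ends + 1L] - cxy[starts]
  vals <- (sxy - sx * sy / w) / (w - 1)
  center <- (starts + ends) / 2
  structure(list(values = vals, times = (center - 1) / fs,
                 center_index = center, window_samples = w,
                 stride_samples = s, sampling_rate = fs),
            class = "covariance_series")
}

#' @export
print.covariance_series <- function(x, ...) {
  cat(sprintf("<covariance_series> %d windows of %d samples (stride %d), mean %.3g nm^2\n",
              length(x$values), x$window_samples, x$stride_samples,
              mean(x$values)))
  invisible(x)
}

# two-component Gaussian mixture by EM with deterministic quantile
# initialization (no RNG in the analysis path)
gmm2 <- function(v, max_iter = 300L, tol = 1e-10) {
  # the bound mode can hold well under 10% of the windows, so seed the lower
  # component deep in the left tail rather than at a central quantile
  mu <- unname(stats::quantile(v, c(0.02, 0.60)))
  sd0 <- max((mu[2] - mu[1]) / 4, stats::sd(v) / 20, 1e-12)
  sdv <- c(sd0, sd0)
  pi1 <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(v, mu[1], sdv[1])
    d2 <- (1 - pi1) * stats::dnorm(v, mu[2], sdv[2])
    tot <- d1 + d2
    tot[tot <= 0] <- .Machine$double.xmin
    g <- d1 / tot
    pi1 <- mean(g)
    if (pi1 < 1e-8 || pi1 > 1 - 1e-8) break
    mu[1] <- sum(g * v) / sum(g)
    mu[2] <- sum((1 - g) * v) / sum(1 - g)
    sdv[1] <- sqrt(sum(g * (v - mu[1])^2) / sum(g))
    sdv[2] <- sqrt(sum((1 - g) * (v - mu[2])^2) / sum(1 - g))
    sdv <- pmax(sdv, 1e-12)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  o <- order(mu)
  list(mu = mu[o], sd = sdv[o], weight = c(pi1, 1 - pi1)[o])
}

#' Automatic hysteresis thresholds from the covariance histogram
#'
#' Fits a two-component Gaussian mixture to the covariance values (bound mode
#' low, unbound mode high) and places the opening threshold at
#' `mu_bound + sd_bound` and the closing threshold at
#' `mu_unbound - sd_unbound`.  When the two modes do not separate (their
#' means closer than the sum of their SDs, or a vanishing component) the
#' function falls back to the 30%/70% quantile span with a warning; the
#' result then carries `attr(, "fallback") = TRUE`.
#'
#' @param cov a [windowed_covariance()] result.
#' @return named numeric `c(low, high)` nm^2, with attributes `mixture`
#'   (fitted components) and `fallback`.
#' @export
auto_thresholds <- function(cov) {
  if (!inherits(cov, "covariance_series"))
    abort_validation("`cov` must be a covariance_series")
  v <- cov$values
  if (diff(range(v)) <= 0)
    abort_validation("degenerate covariance series: all values equal")
  if (length(v) > 50000L) {
    idx <- round(seq(1L, length(v), length.out = 50000L))
    vfit <- v[idx]
  } else vfit <- v
  fit <- gmm2(vfit)
  sep <- (fit$mu[2] - fit$mu[1]) > (fit$sd[1] + fit$sd[2]) &&
    all(fit$weight > 0.02)
  if (sep) {
    low <- fit$mu[1] + fit$sd[1]
    high <- fit$mu[2] - fit$sd[2]
    fallback <- FALSE
  }
  if (!sep || low >= high) {
    warning("covariance modes did not separate; falling back to 30%/70% quantiles",
            call. = FALSE)
    q <- unname(stats::quantile(v, c(0.3, 0.7)))
    low <- q[1]; high <- q[2]
    fallback <- TRUE
  }
  structure(c(low = low, high = high), mixture = fit, fallback = fallback)
}

#' Detect binding events by covariance hysteresis
#'
#' An event opens when the windowed covariance falls below `low_threshold`
#' and closes when it rises back above `high_threshold`; events shorter than
#' `min_duration_s` are discarded, as is an event still open at the end of
#' the series.  Event boundaries are reported on the original sample clock
#' (the centers of the opening and closing windows); follow with
#' [refine_events()] for sample-resolution boundaries.
#'
#' @param cov a [windowed_covariance()] result.
#' @param low_threshold,high_threshold nm^2, `low < high` (see
#'   [auto_thresholds()]).
#' @param min_duration_s minimum event duration, s.
#' @return an [event_set()].
#' @export
detect_events <- function(cov, low_threshold, high_threshold,
                          min_duration_s = 0.020) {
  if (!inherits(cov, "covariance_series"))
    abort_validation("`cov` must be a covariance_series")
  if (low_threshold >= high_threshold)
    abort_validation("thresholds inverted: low (%g) must be < high (%g)",
                     low_threshold, high_threshold)
  v <- cov$values
  ci <- cov$center_index
  open <- FALSE
  start <- numeric(0); end <- numeric(0); cur <- NA_real_
  for (i in seq_along(v)) {
    if (!open && v[i] < low_threshold) {
      open <- TRUE
      cur <- ci[i]
    } else if (open && v[i] > high_threshold) {
      open <- FALSE
      start <- c(start, cur)
      end <- c(end, ci[i])
    }
  }
  s <- round(start); e <- round(end)
  keep <- (e - s) / cov$sampling_rate >= min_duration_s
  event_set(s[keep], e[keep], cov$sampling_rate,
            thresholds = c(low_threshold, high_threshold),
            min_duration_s = min_duration_s)
}

# Gaussian changepoint (mean and variance both free on each side) on segment
# y; returns the split index (last sample of the left segment), searched with
# a margin of `m` samples from either edge. Vectorized over candidate splits.
changepoint_split <- function(y, m = 10L) {
  n <- length(y)
  if (n < 2L * m + 2L) return(NA_integer_)
  cy <- cumsum(y)
  cy2 <- cumsum(y * y)
  i <- m:(n - m)               # candidate left-segment lengths
  n1 <- i
  n2 <- n - i
  s1 <- cy[i]
  s2 <- cy[n] - s1
  q1 <- cy2[i]
  q2 <- cy2[n] - q1
  v1 <- pmax(q1 / n1 - (s1 / n1)^2, 1e-12)
  v2 <- pmax(q2 / n2 - (s2 / n2)^2, 1e-12)
  obj <- n1 * log(v1) + n2 * log(v2)
  i[which.min(obj)]
}

#' Refine event boundaries at sample resolution
#'
#' Covariance-based detection locates events only to within the covariance
#' window.  For each event this re-estimates the start and end as a Gaussian
#' changepoint (both the mean and the variance of the bead signal change at
#' binding) on the mean bead position within `search_s` of the coarse
#' boundary.  Events whose refined boundaries would collide with a neighbour
#' keep their coarse boundaries.
#'
#' The search windows are asymmetric because hysteresis detection is late by
#' construction: the covariance only falls once most of a window is bound, so
#' the true start lies up to about two covariance windows *before* the coarse
#' start, while the true end sits within about one window of the coarse end.
#'
#' @param rec the [trap_recording()] the events came from.
#' @param events an [event_set()].
#' @param start_search_s `(before, after)` search extent around the coarse
#'   start, s.
#' @param end_search_s `(before, after)` search extent around the coarse
#'   end, s.
#' @return an [event_set()] with refined boundaries.
#' @export
refine_events <- function(rec, events, start_search_s = c(0.024, 0.006),
                          end_search_s = c(0.020, 0.008)) {
  if (!inherits(rec, "trap_recording"))
    abort_validation("`rec` must be a trap_recording")
  if (!inherits(events, "event_set"))
    abort_validation("`events` must be an event_set")
  if (!nrow(events)) return(events)
  p <- dumbbell_position(rec)
  fs <- attr(events, "sampling_rate")
  n <- length(p)
  refine_one <- function(idx, before, after) {
    a <- max(1L, as.integer(idx - round(before * fs)))
    b <- min(n, as.integer(idx + round(after * fs)))
    cp <- changepoint_split(p[a:b])
    if (is.na(cp)) as.integer(idx) else a + cp - 1L
  }
  s <- events$start_index
  e <- events$end_index
  rs <- vapply(s, refine_one, integer(1),
               before = start_search_s[1], after = start_search_s[2])
  re <- vapply(e, refine_one, integer(1),
               before = end_search_s[1], after = end_search_s[2])
  bad <- re <= rs
  rs[bad] <- s[bad]; re[bad] <- e[bad]
  if (nrow(events) > 1L) {
    coll <- c(FALSE, rs[-1] < re[-length(re)])
    rs[coll] <- s[coll]; re[coll] <- e[coll]
  }
  event_set(rs, re, fs, thresholds = attr(events, "thresholds"),
            min_duration_s = attr(events, "min_duration_s"))
}

#' Match detected events against ground truth
#'
#' Utility for validating detection on synthetic recordings: a true event is
#' recovered when some detected event overlaps at least `min_overlap` of its
#' span, and a detected event is true when matched the same way.
#'
#' @param events an [event_set()] of detections.
#' @param truth ground-truth data.frame with `start_s`, `end_s`.
#' @param sampling_rate Hz.
#' @param min_overlap required overlap fraction of the true interval.
#' @return list with `recall`, `precision`, `n_true`, `n_detected`.
#' @export
match_events <- function(events, truth, sampling_rate,
                         min_overlap = 0.5) {
  if (!nrow(truth))
    return(list(recall = NA_real_, precision = if (nrow(events)) 0 else NA_real_,
                n_true = 0L, n_detected = nrow(events)))
  ds <- events$start_index / sampling_rate
  de <- events$end_index / sampling_rate
  overlap_frac <- function(a0, a1) {
    if (!length(ds)) return(0)
    ov <- pmax(0, pmin(a1, de) - pmax(a0, ds))
    max(ov) / (a1 - a0)
  }
  rec_hit <- mapply(overlap_frac, truth$start_s, truth$end_s) >= min_overlap
  prec_hit <- if (length(ds)) mapply(function(b0, b1) {
    ov <- pmax(0, pmin(b1, truth$end_s) - pmax(b0, truth$start_s))
    max(ov) / (b1 - b0)
  }, ds, de) >= min_overlap else logical(0)
  list(recall = mean(rec_hit),
       precision = if (length(prec_hit)) mean(prec_hit) else NA_real_,
       n_true = nrow(truth), n_detected = nrow(events))
}
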