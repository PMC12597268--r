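test_that("windowed covariance: identity, symmetry, independence, validation", {
  set.seed(1)
  x <- as.numeric(arima.sim(list(ar = 0.9), 5000))
  rec <- trap_recording(x, x, sampling_rate = 1000)
  cov <- windowed_covariance(rec, window_s = 0.1)
  # identical series: covariance equals the windowed variance, >= 0
  v <- vapply(seq_along(cov$values), function(i) {
    s <- (i - 1) * cov$stride_samples + 1
    var(x[s:(s + cov$window_samples - 1)])
  }, numeric(1))
  expect_equal(cov$values, v, tolerance = 1e-12)
  expect_true(all(cov$values >= 0))

  y <- rnorm(5000)
  r1 <- trap_recording(x, y, 1000)
  r2 <- trap_recording(y, x, 1000)
  expect_equal(windowed_covariance(r1, 0.1)$values,
               windowed_covariance(r2, 0.1)$values)

  # independent unit-variance white noise: mean covariance near zero
  set.seed(2)
  rw <- trap_recording(rnorm(50000), rnorm(50000), 20000)
  cw <- windowed_covariance(rw, window_s = 0.05)  # 1000-sample windows
  expect_lt(abs(mean(cw$values)), 0.1)

  expect_error(windowed_covariance(rw, window_s = 10), "longer")
  expect_error(windowed_covariance(rw, window_s = 2e-4), ">= 10")
  expect_error(windowed_covariance(rw, 0.01, stride_s = 0.02), "stride")
})

test_that("hysteresis detection: trivial cases and output invariants", {
  fake_cov <- function(values, fs = 1000, w = 10L, s = 5L) {
    starts <- seq(1L, by = s, length.out = length(values))
    structure(list(values = values, times = (starts + (w - 1) / 2 - 1) / fs,
                   center_index = starts + (w - 1) / 2, window_samples = w,
                   stride_samples = s, sampling_rate = fs),
              class = "covariance_series")
  }
  # everywhere above the high threshold: empty set
  cov <- fake_cov(rep(30, 100))
  ev <- detect_events(cov, 5, 20, 0.01)
  expect_identical(nrow(ev), 0L)
  # one dip shorter than min_duration: filtered
  vv <- rep(30, 100); vv[40:41] <- 1
  expect_identical(nrow(detect_events(fake_cov(vv), 5, 20, 0.05)), 0L)
  expect_identical(nrow(detect_events(fake_cov(vv), 5, 20, 0.005)), 1L)
  expect_error(detect_events(cov, 20, 5, 0.01), "inverted")

  # random series: events disjoint, ordered, all >= min_duration
  set.seed(33)
  for (i in 1:20) {
    vals <- runif(400, 0, 40)
    ev <- detect_events(fake_cov(vals), 10, 25, 0.02)
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$start_index) > 0))
      expect_true(all(ev$start_index[-1] >= ev$end_index[-nrow(ev)]))
    }
    expect_true(all(ev$duration_s >= 0.02))
  }
})

test_that("auto thresholds: separated modes, fallback, degenerate input", {
  fake_cov <- function(values) {
    structure(list(values = values, times = seq_along(values) / 1000,
                   center_index = seq_along(values), window_samples = 10L,
                   stride_samples = 5L, sampling_rate = 1000),
              class = "covariance_series")
  }
  set.seed(5)
  v <- c(rnorm(400, 5, 0.5), rnorm(1600, 50, 3))
  th <- auto_thresholds(fake_cov(v))
  expect_false(attr(th, "fallback"))
  expect_lt(th["low"], th["high"])
  expect_lt(th["low"], 50)
  expect_gt(th["high"], 5)
  # thresholds near the generator-derived ideal edges (mu_b + sd_b = 5.5,
  # mu_u - sd_u = 47), within 20%
  expect_lt(abs(th["low"] - 5.5) / 5.5, 0.2)
  expect_lt(abs(th["high"] - 47) / 47, 0.2)

  expect_warning(thu <- auto_thresholds(fake_cov(rnorm(2000, 20, 2))),
                 "fall")
  expect_true(attr(thu, "fallback"))
  expect_error(auto_thresholds(fake_cov(rep(7, 100))), "degenerate")
})

test_that("detection on a synthetic recording: recall and precision >= 90%", {
  rec <- simulate_trap_recording(trap_sim_params(duration_s = 120, seed = 42))
  an <- analyze_trap_recording(rec, fit = FALSE)
  m <- match_events(an$events, rec$truth, rec$sampling_rate)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.9)
  # refinement brings boundaries closer to the truth than the coarse clock
  cov <- an$covariance
  th <- an$thresholds
  coarse <- detect_events(cov, th[1], th[2], 0.02)
  fs <- rec$sampling_rate
  nearest <- function(x, y) vapply(x, function(z) y[which.min(abs(y - z))],
                                   numeric(1))
  coarse_err <- abs(coarse$start_index / fs -
                      nearest(coarse$start_index / fs, rec$truth$start_s))
  fine_err <- abs(an$events$start_index / fs -
                    nearest(an$events$start_index / fs, rec$truth$start_s))
  expect_lt(mean(fine_err), mean(coarse_err))
  expect_lt(mean(fine_err), 0.002)
})

test_that("exponential duration fit: closed form, truncation, oracle", {
  f <- fit_exponential_rate(rep(0.2, 100), min_duration = 0)
  expect_equal(f$rate, 5)
  expect_equal(f$stderr, 5 / 10)

  set.seed(14)
  d <- rexp(2000, 10)
  dk <- d[d >= 0.05]
  ft <- fit_exponential_rate(dk, min_duration = 0.05)
  expect_lt(abs(ft$rate - 10) / 10, 0.05)
  # naive 1/mean is biased low on the truncated sample
  expect_lt(1 / mean(dk), 0.8 * 10)
  # independent oracle: direct likelihood maximization
  nll <- function(r) -sum(log(r) - r * (dk - 0.05))
  orc <- optimize(nll, c(0.1, 100))$minimum
  expect_equal(ft$rate, orc, tolerance = 1e-3)

  # recovery at the published event count and detachment rate
  d516 <- simulate_durations(5.9, 516, seed = 12)
  f516 <- fit_exponential_rate(d516)
  expect_lt(abs(f516$rate - 5.9), 2 * f516$stderr)

  expect_error(fit_exponential_rate(rep(0.1, 5)), ">= 10")
  expect_error(fit_exponential_rate(rep(0.1, 50), min_duration = 0.1),
               "truncation")
})

test_that("ensemble average: rectangular event, single event, two-level rise", {
  # single noiseless rectangular event of 5 nm: forward average is flat 5
  ev1 <- data.frame(start_s = 1, trans_s = 1, end_s = 1.4)
  rec <- make_clean_recording(ev1, s1 = 5, s2 = 0, duration_s = 3)
  es <- event_set(floor(1 * 2000) + 1, floor(1.4 * 2000), 2000)
  fwd <- ensemble_average(rec, es, "forward", span_s = 0.2)
  expect_equal(fwd$mean_position, rep(5, length(fwd$times)))
  expect_equal(fwd$n_events, 1L)
  # averaging one event returns that event's own (baseline-subtracted) trace
  p <- dumbbell_position(rec)
  seg <- p[es$start_index[1]:(es$start_index[1] + length(fwd$times) - 1)]
  expect_equal(fwd$mean_position, seg - 0)

  # noiseless two-level events with exponential state-1 dwells at 60 s^-1:
  # the forward average follows s1 + s2 (1 - exp(-k1 t)); rate within 10%
  set.seed(7)
  n_ev <- 400
  starts <- (seq_len(n_ev) - 1) * 0.6 + 0.3
  t1 <- rexp(n_ev, 60)
  evs <- data.frame(start_s = starts, trans_s = starts + t1,
                    end_s = starts + t1 + 0.35)
  rec2 <- make_clean_recording(evs, s1 = 4, s2 = 1,
                               duration_s = max(evs$end_s) + 0.5)
  es2 <- event_set(floor(evs$start_s * 2000) + 1, floor(evs$end_s * 2000), 2000)
  fwd2 <- ensemble_average(rec2, es2, "forward", span_s = 0.15)
  expect_lt(abs(fwd2$mean_position[1] - 4), 0.15)
  expect_lt(abs(mean(tail(fwd2$mean_position, 50)) - 5), 0.05)
  rates <- fit_ensemble_rates(fwd2,
                              ensemble_average(rec2, es2, "reverse", 0.3),
                              guard_s = 0.001)
  expect_lt(abs(rates$k1$rate - 60) / 60, 0.10)

  expect_error(ensemble_average(rec, event_set(integer(0), integer(0), 2000),
                                "forward"), "non-empty")
})

test_that("ensemble rate fits: exact curve to 0.1%, degenerate amplitude flagged", {
  t <- seq(0, 0.15, by = 1 / 2000)
  fab <- function(mode, y) structure(
    list(mode = mode, times = if (mode == "forward") t else -rev(t),
         mean_position = y, sd_position = rep(0.01, length(t)),
         n_events_per_bin = rep(100, length(t)), n_events = 100,
         span_s = 0.15, sampling_rate = 2000),
    class = "ensemble_average")
  fwd <- fab("forward", 4 + 1 * (1 - exp(-63.1 * t)))
  # reverse times are -rev(t), so |time| at index i is rev(t)[i]
  rev <- fab("reverse", 4 + 1 * exp(-63.1 * rev(t)))
  rt <- fit_ensemble_rates(fwd, rev, guard_s = 0)
  expect_lt(abs(rt$k1$rate - 63.1) / 63.1, 0.001)
  expect_lt(abs(rt$k2$rate - 63.1) / 63.1, 0.001)

  flat <- fab("reverse", rep(5, length(t)))
  rt2 <- fit_ensemble_rates(fwd, flat, guard_s = 0)
  expect_identical(rt2$k2$flag, "non-identifiable")
})

test_that("substep measurement: exact two-level event and exclusion rule", {
  # 4 nm for 50 ms then 5 nm for 150 ms; windows 5 ms -> 4.00 + 1.00
  ev <- data.frame(start_s = 1, trans_s = 1.05, end_s = 1.2)
  rec <- make_clean_recording(ev, s1 = 4, s2 = 1, duration_s = 3)
  es <- event_set(floor(1 * 2000) + 1, floor(1.2 * 2000), 2000)
  st <- measure_substeps(rec, es, early_window_s = 0.005,
                         late_window_s = 0.005, start_guard_s = 0,
                         end_guard_s = 0.001)
  expect_equal(st$substep1_nm, 4)
  expect_equal(st$substep2_nm, 1)
  expect_equal(st$total_nm, 5)

  # events shorter than the window sum are excluded from substep 2;
  # the count matches the duration filter on ground truth
  evs <- data.frame(start_s = c(1, 2, 3), trans_s = c(1.001, 2.05, 3.05),
                    end_s = c(1.005, 2.3, 3.25))
  rec2 <- make_clean_recording(evs, duration_s = 4)
  es2 <- event_set(floor(evs$start_s * 2000) + 1, floor(evs$end_s * 2000), 2000)
  st2 <- measure_substeps(rec2, es2)
  s <- attr(st2, "summary")
  # oracle: early 2 ms + late 5 ms + end guard 1 ms = 8 ms minimum
  expect_identical(s$n_excluded,
                   sum((evs$end_s - evs$start_s) < 0.008))
  expect_identical(s$n, 3L)
  expect_identical(s$n_total, 2L)

  # no qualifying event (no pre-event baseline window)
  ev0 <- data.frame(start_s = 0.001, trans_s = 0.002, end_s = 0.05)
  rec0 <- make_clean_recording(ev0, duration_s = 0.2)
  es0 <- event_set(floor(0.001 * 2000) + 1, floor(0.05 * 2000), 2000)
  expect_error(measure_substeps(rec0, es0), "baseline|qualif")
})

test_that("substep recovery on the stochastic generator", {
  rec <- simulate_trap_recording(trap_sim_params(duration_s = 240, seed = 19))
  an <- analyze_trap_recording(rec, fit = FALSE)
  s <- attr(an$substeps, "summary")
  expect_lt(abs(s$mean_substep1 - 4.03), 0.3)
  expect_lt(abs(s$mean_substep2 - 1.10), 0.3)
})

test_that("pooling ensembles and substep tables preserves bin-wise totals", {
  rec <- simulate_trap_recording(trap_sim_params(duration_s = 60, seed = 3))
  an <- analyze_trap_recording(rec, fit = FALSE)
  # pooling an analysis with itself doubles counts, keeps the mean
  pooled <- pool_ensemble_averages(list(an$forward, an$forward))
  expect_equal(pooled$mean_position, an$forward$mean_position)
  expect_equal(pooled$n_events_per_bin, 2 * an$forward$n_events_per_bin)
  pst <- pool_substep_tables(list(an$substeps, an$substeps))
  expect_equal(attr(pst, "summary")$mean_substep1,
               attr(an$substeps, "summary")$mean_substep1)
  expect_identical(attr(pst, "summary")$n, 2L * attr(an$substeps, "summary")$n)
})
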