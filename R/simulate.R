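#' Parameters of the synthetic trap-recording generator
#'
#' The generator emulates an actin dumbbell held by two optical traps over a
#' single myosin: a mean-reverting (Ornstein-Uhlenbeck) fluctuation shared by
#' both beads (the correlated dumbbell motion that covariance detection keys
#' on), independent white measurement noise per bead, and Poisson-arriving
#' binding events.  During an event the shared fluctuation is attenuated
#' (bead-bead covariance drops), the mean position steps by `substep1_nm` at
#' attachment and by a further `substep2_nm` after an exponential state-1
#' dwell (rate `k1_hz`, the ADP-release-limited transition); detachment
#' follows an exponential state-2 dwell (rate `k2_hz`, ATP-binding limited:
#' at 1 uM ATP and a second-order binding rate of 4.6 uM^-1 s^-1 the implied
#' rate is 4.6 s^-1; the default 4.94 s^-1 is the measured value).
#'
#' @param sampling_rate Hz (default 20000).
#' @param duration_s recording length, s (default 60).
#' @param shared_sd_nm SD of the shared (unbound) fluctuation, nm (default 5).
#' @param independent_sd_nm per-bead white-noise SD, nm (default 2).
#' @param tau_s relaxation time of the shared fluctuation, s (default 5e-4).
#' @param bound_attenuation multiplier on the shared SD while bound,
#'   in (0, 1) (default 0.3; bound covariance = attenuation^2 x unbound).
#' @param arrival_rate_hz Poisson event arrival rate, s^-1 (default 0.5).
#' @param substep1_nm,substep2_nm power-stroke substeps, nm
#'   (defaults 4.03 and 1.10).
#' @param k1_hz state-1 -> state-2 rate, s^-1 (default 63.1).
#' @param k2_hz state-2 -> detachment rate, s^-1; `NULL` derives it as
#'   `atp_binding_per_um_s * atp_um` (default 4.94).
#' @param atp_um ATP concentration, uM (default 1).
#' @param atp_binding_per_um_s second-order ATP binding rate, uM^-1 s^-1
#'   (default 4.6).
#' @param seed integer seed.
#' @return list of class `trap_sim_params`.
#' @export
trap_sim_params <- function(sampling_rate = 20000, duration_s = 60,
                            shared_sd_nm = 5, independent_sd_nm = 2,
                            tau_s = 5e-4, bound_attenuation = 0.3,
                            arrival_rate_hz = 0.5,
                            substep1_nm = 4.03, substep2_nm = 1.10,
                            k1_hz = 63.1, k2_hz = 4.94,
                            atp_um = 1, atp_binding_per_um_s = 4.6,
                            seed = 1L) {
  if (is.null(k2_hz)) k2_hz <- atp_binding_per_um_s * atp_um
  p <- list(sampling_rate = sampling_rate, duration_s = duration_s,
            shared_sd_nm = shared_sd_nm, independent_sd_nm = independent_sd_nm,
            tau_s = tau_s, bound_attenuation = bound_attenuation,
            arrival_rate_hz = arrival_rate_hz,
            substep1_nm = substep1_nm, substep2_nm = substep2_nm,
            k1_hz = k1_hz, k2_hz = k2_hz, atp_um = atp_um,
            atp_binding_per_um_s = atp_binding_per_um_s,
            seed = as.integer(seed))
  for (nm in c("sampling_rate", "duration_s", "shared_sd_nm", "tau_s",
               "k1_hz", "k2_hz", "atp_binding_per_um_s"))
    assert_scalar_number(p[[nm]], nm, positive = TRUE)
  assert_scalar_number(p$independent_sd_nm, "independent_sd_nm", nonneg = TRUE)
  assert_scalar_number(p$arrival_rate_hz, "arrival_rate_hz", nonneg = TRUE)
  if (p$bound_attenuation <= 0 || p$bound_attenuation >= 1)
    abort_validation("`bound_attenuation` must lie in (0, 1)")
  structure(p, class = "trap_sim_params")
}

#' Simulate a three-bead trap recording with ground truth
#'
#' Events arrive as a Poisson process; arrivals falling inside an ongoing
#' event are discarded (single-molecule condition), and events that would run
#' past the end of the recording are dropped from the ground truth.  The
#' shared fluctuation uses the exact Ornstein-Uhlenbeck discretization
#' (per-step autoregression `exp(-dt/tau)`), so its stationary variance is
#' analytic.  Both beads report the myosin-induced displacement identically
#' (rigid-dumbbell approximation) with positive step polarity.
#'
#' @param p a [trap_sim_params()] (or arguments for it via `...`).
#' @param ... passed to [trap_sim_params()] when `p` is missing.
#' @return a [trap_recording()] whose `truth` holds the generated events.
#' @examples
#' rec <- simulate_trap_recording(trap_sim_params(duration_s = 5, seed = 7))
#' rec
#' @export
simulate_trap_recording <- function(p = NULL, ...) {
  if (is.null(p)) p <- trap_sim_params(...)
  if (!inherits(p, "trap_sim_params"))
    abort_validation("`p` must come from trap_sim_params()")
  if (p$arrival_rate_hz > 0 && p$duration_s < 10 / p$arrival_rate_hz)
    warning(sprintf("duration %.3g s is short relative to 10/arrival_rate = %.3g s",
                    p$duration_s, 10 / p$arrival_rate_hz), call. = FALSE)
  set.seed(p$seed)
  fs <- p$sampling_rate
  n <- floor(p$duration_s * fs)
  dt <- 1 / fs

  # --- event schedule -------------------------------------------------------
  starts <- trans <- ends <- numeric(0)
  if (p$arrival_rate_hz > 0) {
    t_arr <- stats::rexp(1, p$arrival_rate_hz)
    cur_end <- -Inf
    while (t_arr < p$duration_s) {
      if (t_arr >= cur_end) {
        t1 <- stats::rexp(1, p$k1_hz)
        t2 <- stats::rexp(1, p$k2_hz)
        e <- t_arr + t1 + t2
        cur_end <- e
        if (e < p$duration_s) {
          starts <- c(starts, t_arr)
          trans <- c(trans, t_arr + t1)
          ends <- c(ends, e)
        }
      }
      t_arr <- t_arr + stats::rexp(1, p$arrival_rate_hz)
    }
  }
  truth <- data.frame(start_s = starts, trans_s = trans, end_s = ends,
                      substep1_nm = rep(p$substep1_nm, length(starts)),
                      substep2_nm = rep(p$substep2_nm, length(starts)))

  # --- mean displacement and time-varying shared SD -------------------------
  d <- numeric(n)
  sig <- rep(p$shared_sd_nm, n)
  if (nrow(truth)) {
    i_start <- pmin(floor(truth$start_s * fs) + 1L, n)
    i_trans <- pmin(floor(truth$trans_s * fs) + 1L, n)
    i_end <- pmin(floor(truth$end_s * fs), n)
    for (j in seq_len(nrow(truth))) {
      d[i_start[j]:i_end[j]] <- p$substep1_nm
      if (i_trans[j] <= i_end[j])
        d[i_trans[j]:i_end[j]] <- p$substep1_nm + p$substep2_nm
      sig[i_start[j]:i_end[j]] <- p$shared_sd_nm * p$bound_attenuation
    }
  }

  # --- noise ----------------------------------------------------------------
  rho <- exp(-dt / p$tau_s)
  innov <- stats::rnorm(n, 0, sqrt(1 - rho^2))
  u <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                init = stats::rnorm(1)))
  shared <- u * sig
  bead1 <- d + shared + stats::rnorm(n, 0, p$independent_sd_nm)
  bead2 <- d + shared + stats::rnorm(n, 0, p$independent_sd_nm)

  trap_recording(bead1, bead2, sampling_rate = fs, atp = p$atp_um,
                 truth = truth,
                 metadata = list(params = unclass(p), seed = p$seed))
}

#' Simulate attachment durations
#'
#' i.i.d. exponential dwell times, the single-exponential null against which
#' attachment-duration fits are tested.
#'
#' @param rate s^-1, > 0.
#' @param n sample size, >= 1.
#' @param seed integer seed.
#' @return numeric vector of durations, s.
#' @export
simulate_durations <- function(rate, n, seed = 1L) {
  assert_scalar_number(rate, "rate", positive = TRUE)
  if (!is.numeric(n) || n < 1) abort_validation("`n` must be >= 1")
  set.seed(as.integer(seed))
  stats::rexp(as.integer(n), rate)
}

#' Simulate a mixture-motility dataset from the mechanical-interaction model
#'
#' For every mole fraction and replicate, velocity = model curve times
#' `(1 + eps)` with `eps ~ Normal(0, noise_cv)`, truncated at zero.
#'
#' @param pair a [mixture_pair()] (the generating force ratio lives here).
#' @param k_grid mole fractions (default 6 points spanning `[0, 1]`).
#' @param noise_cv fractional SD of the multiplicative noise (default 0.05).
#' @param replicates technical replicates per mole fraction (default 3).
#' @param seed integer seed.
#' @param aggregate collapse replicates to per-k mean/sd/n (default FALSE).
#' @return a `mixture_dataset` (replicate-level unless `aggregate`).
#' @export
simulate_mixture_dataset <- function(pair, k_grid = seq(0, 1, length.out = 6),
                                     noise_cv = 0.05, replicates = 3L,
                                     seed = 1L, aggregate = FALSE) {
  if (!inherits(pair, "mixture_pair"))
    abort_validation("`pair` must be a mixture_pair")
  assert_scalar_number(noise_cv, "noise_cv", nonneg = TRUE)
  if (!is.numeric(replicates) || replicates < 1)
    abort_validation("`replicates` must be >= 1")
  replicates <- as.integer(replicates)
  if (!is.numeric(k_grid) || !length(k_grid) || any(k_grid < 0 | k_grid > 1))
    abort_validation("`k_grid` must be mole fractions in [0, 1]")
  v0 <- solve_mixture_velocity(pair, k_grid)
  set.seed(as.integer(seed))
  k <- rep(k_grid, each = replicates)
  eps <- stats::rnorm(length(k), 0, noise_cv)
  v <- pmax(rep(v0, each = replicates) * (1 + eps), 0)
  out <- as_mixture_dataset(
    data.frame(k = k, velocity_um_s = v, n = 1L),
    metadata = list(pair = sprintf("%s/%s", pair$slow$name, pair$fast$name),
                    force_ratio = pair$force_ratio, noise_cv = noise_cv,
                    replicates = replicates, seed = as.integer(seed))
  )
  if (aggregate) aggregate_mixture_dataset(out) else out
}

#' Simulate per-filament gliding speeds
#'
#' Normal sample truncated at zero (gliding speeds are nonnegative and
#' near-normal), unit weights.
#'
#' @param mean,sd um/s; `mean > 0`, `sd >= 0`.
#' @param n filaments.
#' @param seed integer seed.
#' @param label,replicate passed to [speed_sample()].
#' @return a [speed_sample()].
#' @export
simulate_gliding_speeds <- function(mean, sd, n, seed = 1L, label = "",
                                    replicate = NULL) {
  assert_scalar_number(mean, "mean", positive = TRUE)
  assert_scalar_number(sd, "sd", nonneg = TRUE)
  if (!is.numeric(n) || n < 1) abort_validation("`n` must be >= 1")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  speeds <- stats::rnorm(n, mean, sd)
  while (any(speeds < 0))
    speeds[speeds < 0] <- stats::rnorm(sum(speeds < 0), mean, sd)
  speed_sample(speeds, weights = 1, label = label, replicate = replicate)
}
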