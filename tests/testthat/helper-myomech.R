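# Shared fixtures and independent oracles for the test suite.

# Motility-table constants used throughout (um/s; dimensionless curvatures)
tbl_wt <- function() motor_species("WT-cHMM", 1.69, 0.17)
tbl_s532p <- function() motor_species("S532P-cHMM", 0.62, 0.17)
tbl_sk <- function() motor_species("Sk-myosin", 6.57, 0.25)

# Independent oracle: evaluate the three quadratic coefficients by direct
# arithmetic on the printed formulas (no shared code with the package).
oracle_coefficients <- function(cs, cf, R, vs, vf, k) {
  c(a1 = -(cs * R * (1 - k)) - k * cf,
    a2 = cs * R * (1 - k) * (vs - vf * cf) + k * cf * (vf - vs * cs),
    a3 = cs * cf * vs * vf * ((1 - k) * R + k))
}

# Independent oracle: sign-change bisection root finder on [0, 2 max(vs,vf)].
oracle_root <- function(cs, cf, R, vs, vf, k, iter = 200) {
  co <- oracle_coefficients(cs, cf, R, vs, vf, k)
  f <- function(v) co["a1"] * v^2 + co["a2"] * v + co["a3"]
  lo <- 0; hi <- 2 * max(vs, vf)
  stopifnot(sign(f(lo)) != sign(f(hi)))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Noise-free trap recording with prescribed events, for exact-value tests.
# events: data.frame(start_s, trans_s, end_s); steps s1/s2 in nm.
make_clean_recording <- function(events, s1 = 4, s2 = 1, duration_s = 2,
                                 fs = 2000) {
  n <- round(duration_s * fs)
  d <- numeric(n)
  for (j in seq_len(nrow(events))) {
    i0 <- floor(events$start_s[j] * fs) + 1L
    it <- floor(events$trans_s[j] * fs) + 1L
    i1 <- floor(events$end_s[j] * fs)
    d[i0:i1] <- s1
    if (it <= i1) d[it:i1] <- s1 + s2
  }
  trap_recording(d, d, sampling_rate = fs)
}

events_from_truth <- function(rec) {
  fs <- rec$sampling_rate
  event_set(floor(rec$truth$start_s * fs) + 1L,
            floor(rec$truth$end_s * fs), fs)
}
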