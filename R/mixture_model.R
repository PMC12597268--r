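#' Quadratic coefficients of the mixed-motor velocity equation
#'
#' Actin gliding velocity V over a mixed surface of a slow and a fast myosin
#' satisfies the quadratic `A1 V^2 + A2 V + A3 = 0`, whose coefficients
#' depend on the mole fraction `k` of the fast motor, the two unloaded
#' velocities, the two Hill curvatures, and the force ratio `R = F0s/F0f`:
#'
#' \deqn{A1 = -[cs R (1-k)] - k cf}
#' \deqn{A2 = cs R (1-k) (Vs - Vf cf) + k cf (Vf - Vs cs)}
#' \deqn{A3 = cs cf Vs Vf [(1-k) R + k]}
#'
#' with `cs = a_s/F0s`, `cf = a_f/F0f`.  For any valid pair and `k` in
#' `[0, 1]`, `A1 < 0` and `A3 > 0`, so the quadratic has exactly one
#' positive root.
#'
#' @param pair a [mixture_pair()].
#' @param k mole fraction(s) of the fast motor, each in `[0, 1]`; vectorized.
#' @return A data.frame with columns `k`, `a1`, `a2`, `a3`.
#' @seealso [solve_mixture_velocity()]
#' @examples
#' pair <- mixture_pair(motor_species("s", 1.69, 0.17),
#'                      motor_species("f", 6.57, 0.25), force_ratio = 3.3)
#' mixture_coefficients(pair, 0.5)
#' @export
mixture_coefficients <- function(pair, k) {
  if (!inherits(pair, "mixture_pair"))
    abort_validation("`pair` must be a mixture_pair")
  if (!is.numeric(k) || length(k) < 1L || anyNA(k))
    abort_validation("`k` must be numeric without NA")
  if (any(k < 0 | k > 1))
    abort_validation("mole fraction `k` must lie in [0, 1]")
  cs <- pair$slow$curvature
  cf <- pair$fast$curvature
  vs <- pair$slow$vmax
  vf <- pair$fast$vmax
  R  <- pair$force_ratio
  a1 <- -(cs * R * (1 - k)) - k * cf
  a2 <- cs * R * (1 - k) * (vs - vf * cf) + k * cf * (vf - vs * cs)
  a3 <- cs * cf * vs * vf * ((1 - k) * R + k)
  data.frame(k = k, a1 = a1, a2 = a2, a3 = a3)
}

#' Gliding velocity of actin over a two-motor mixture
#'
#' Solves the mixed-motor quadratic for its unique positive root.  At the
#' boundaries the roots are analytic: `V(0) = slow$vmax` and
#' `V(1) = fast$vmax`.
#'
#' @inheritParams mixture_coefficients
#' @return Numeric vector of velocities (um/s), one per element of `k`.
#' @examples
#' pair <- mixture_pair(motor_species("s", 1.69, 0.17),
#'                      motor_species("f", 6.57, 0.25), force_ratio = 3.3)
#' solve_mixture_velocity(pair, c(0, 0.5, 1))
#' @export
solve_mixture_velocity <- function(pair, k) {
  co <- mixture_coefficients(pair, k)
  disc <- co$a2^2 - 4 * co$a1 * co$a3
  if (any(disc < -1e-12 * pmax(co$a2^2, 1)))
    stop("internal inconsistency: negative discriminant in mixture quadratic")
  disc <- pmax(disc, 0)
  sq <- sqrt(disc)
  # a1 < 0 always holds for valid pairs, so the positive root is
  # (-a2 - sqrt(disc)) / (2 a1); assert positivity rather than trusting the
  # branch at extreme parameters.
  v <- (-co$a2 - sq) / (2 * co$a1)
  bad <- v <= 0 | !is.finite(v)
  if (any(bad)) {
    alt <- (-co$a2 + sq) / (2 * co$a1)
    v[bad] <- alt[bad]
    if (any(v <= 0 | !is.finite(v)))
      stop("internal inconsistency: no positive root of mixture quadratic")
  }
  v
}

#' Predicted velocity-vs-mole-fraction curve
#'
#' @inheritParams mixture_coefficients
#' @param k_grid mole fractions at which to evaluate the model.
#' @return data.frame with columns `k` and `velocity_um_s`.
#' @export
predict_curve <- function(pair, k_grid = seq(0, 1, by = 0.05)) {
  data.frame(k = k_grid,
             velocity_um_s = solve_mixture_velocity(pair, k_grid))
}

#' Equal-force reference curve
#'
#' The model curve with the force ratio forced to 1, i.e. the gliding speed
#' expected if both species produced identical force.  When the fitted ratio
#' exceeds 1 this reference lies above the fitted curve at interior mole
#' fractions, which is the visual signature of the slow motor "braking" the
#' fast one.
#'
#' @param slow,fast [motor_species()] objects.
#' @param k_grid mole fractions.
#' @return data.frame with columns `k` and `velocity_um_s`.
#' @export
equal_force_reference <- function(slow, fast, k_grid = seq(0, 1, by = 0.05)) {
  predict_curve(mixture_pair(slow, fast, force_ratio = 1), k_grid)
}

objective_force_ratio <- function(log_ratio, data, slow, fast, weights) {
  pair <- mixture_pair(slow, fast, force_ratio = exp(log_ratio))
  pred <- solve_mixture_velocity(pair, data$k)
  sum(weights * (data$velocity_um_s - pred)^2)
}

fit_weights <- function(data) {
  unc <- data$uncertainty_um_s
  if (!is.null(unc) && all(is.finite(unc)) && all(unc > 0)) 1 / unc^2
  else rep(1, nrow(data))
}

#' Fit the slow/fast force ratio to a mixture-motility dataset
#'
#' The two species' unloaded velocities and curvatures are held fixed; the
#' only free parameter is the force ratio `F0s/F0f`.  The objective is the
#' inverse-variance-weighted sum of squared residuals between observed mean
#' velocities and the model curve (unweighted when no uncertainties are
#' supplied).  The ratio is located by a log-spaced grid search over
#' `[0.05, 20]` refined with bounded one-dimensional minimization.
#'
#' @param data a `mixture_dataset` (see [as_mixture_dataset()]) or data.frame
#'   with at least columns `k` and `velocity_um_s`; optional
#'   `uncertainty_um_s` supplies weights.
#' @param slow,fast [motor_species()] objects with fixed vmax and curvature.
#' @param bounds search interval for the ratio (default `c(0.05, 20)`).
#' @param n_grid number of log-spaced grid points before refinement.
#' @return A `force_ratio_fit` object: list with `estimate`, `objective_value`,
#'   `fixed_inputs`, `degenerate` flag, and the data used.  `ci95` and
#'   `bootstrap_samples` are filled by [bootstrap_force_ratio()].
#' @examples
#' pair <- mixture_pair(motor_species("s", 1.69, 0.17),
#'                      motor_species("f", 6.57, 0.25), force_ratio = 2)
#' d <- predict_curve(pair, seq(0, 1, length.out = 6))
#' fit <- fit_force_ratio(d, pair$slow, pair$fast)
#' fit$estimate  # 2 to ~1e-6
#' @export
fit_force_ratio <- function(data, slow, fast, bounds = c(0.05, 20),
                            n_grid = 60L) {
  data <- as_mixture_dataset(data)
  if (length(unique(data$k)) < 3L)
    abort_validation("need >= 3 distinct mole fractions to fit (got %d)",
                     length(unique(data$k)))
  w <- fit_weights(data)
  degenerate <- (diff(range(data$velocity_um_s)) <
                   1e-8 * max(abs(data$velocity_um_s), 1)) &&
    abs(slow$vmax - fast$vmax) > 1e-12
  if (degenerate)
    warning("degenerate data: all velocities equal while vmax values differ; ",
            "estimate returned but is not meaningful", call. = FALSE)
  lg <- log(bounds)
  grid <- seq(lg[1], lg[2], length.out = n_grid)
  obj <- vapply(grid, objective_force_ratio, numeric(1),
                data = data, slow = slow, fast = fast, weights = w)
  i <- which.min(obj)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(objective_force_ratio, c(lo, hi),
                         data = data, slow = slow, fast = fast, weights = w,
                         tol = 1e-10)
  structure(list(
    estimate = exp(opt$minimum),
    objective_value = opt$objective,
    ci95 = NULL,
    bootstrap_samples = NULL,
    degenerate = degenerate,
    fixed_inputs = list(
      slow = slow, fast = fast, bounds = bounds,
      weighted = !is.null(data$uncertainty_um_s) && all(is.finite(w))
    ),
    data = data
  ), class = "force_ratio_fit")
}

#' @export
print.force_ratio_fit <- function(x, ...) {
  cat(sprintf("<force_ratio_fit> F0s/F0f = %.3g", x$estimate))
  if (!is.null(x$ci95))
    cat(sprintf("  (95%% CI %.3g - %.3g, %d bootstrap iterations)",
                x$ci95[1], x$ci95[2], length(x$bootstrap_samples)))
  cat(sprintf("\n  objective (weighted SSR): %.4g\n", x$objective_value))
  invisible(x)
}

#' Bootstrap confidence interval for the force ratio
#'
#' Reproduces the fitting protocol in which the 95% CI comes from refitting
#' the model many times while the slow/fast unloaded-velocity ratio is
#' "randomly varied" within its own 95% CI.  The sampling law for that
#' variation is not pinned down by the protocol; this implementation draws
#' it uniformly on `vmax_ratio_ci` (the maximally agnostic choice within the
#' stated interval) and rescales `slow$vmax` while holding `fast$vmax`
#' (the slow species' speed carries the larger relative uncertainty).
#' Optionally the observations themselves are case-resampled within each
#' mole fraction (`resample_observations = TRUE`); the default
#' "footnote-strict" mode perturbs only the vmax ratio.
#'
#' @inheritParams fit_force_ratio
#' @param vmax_ratio_ci length-2 numeric, 95% CI for `slow$vmax/fast$vmax`;
#'   must bracket the point ratio.
#' @param iterations bootstrap iterations (default 1000).
#' @param seed integer seed; all randomness in the bootstrap flows from it.
#' @param resample_observations also case-resample observations within each
#'   `k` (default `FALSE` = footnote-strict).
#' @param vary_vmax which species' vmax absorbs the ratio perturbation,
#'   `"slow"` (default) or `"fast"`.
#' @return A `force_ratio_fit` with `ci95` (2.5/97.5 percentiles) and
#'   `bootstrap_samples` filled in.
#' @export
bootstrap_force_ratio <- function(data, slow, fast, vmax_ratio_ci,
                                  iterations = 1000L, seed = 1L,
                                  resample_observations = FALSE,
                                  vary_vmax = c("slow", "fast"),
                                  bounds = c(0.05, 20)) {
  vary_vmax <- match.arg(vary_vmax)
  data <- as_mixture_dataset(data)
  if (!is.numeric(iterations) || iterations < 1)
    abort_validation("`iterations` must be >= 1")
  iterations <- as.integer(iterations)
  point_ratio <- slow$vmax / fast$vmax
  if (length(vmax_ratio_ci) != 2L || vmax_ratio_ci[1] > vmax_ratio_ci[2])
    abort_validation("`vmax_ratio_ci` must be (low, high) with low <= high")
  if (point_ratio < vmax_ratio_ci[1] - 1e-12 ||
      point_ratio > vmax_ratio_ci[2] + 1e-12)
    abort_validation("vmax_ratio_ci [%g, %g] does not bracket the point ratio %g",
                     vmax_ratio_ci[1], vmax_ratio_ci[2], point_ratio)

  fit0 <- fit_force_ratio(data, slow, fast, bounds = bounds)
  set.seed(as.integer(seed))
  groups <- split(seq_len(nrow(data)), data$k)
  est <- numeric(iterations)
  for (b in seq_len(iterations)) {
    r <- stats::runif(1, vmax_ratio_ci[1], vmax_ratio_ci[2])
    if (vary_vmax == "slow") {
      s_b <- motor_species(slow$name, r * fast$vmax, slow$curvature)
      f_b <- fast
    } else {
      s_b <- slow
      f_b <- motor_species(fast$name, slow$vmax / r, fast$curvature)
    }
    d_b <- data
    if (resample_observations) {
      idx <- unlist(lapply(groups, function(g) {
        if (length(g) == 1L) g else sample(g, length(g), replace = TRUE)
      }), use.names = FALSE)
      d_b <- data[idx, , drop = FALSE]
    }
    # warm-started refinement around the point estimate keeps 1000
    # iterations fast without losing the global grid safeguard
    est[b] <- fit_force_ratio(d_b, s_b, f_b, bounds = bounds,
                              n_grid = 25L)$estimate
  }
  fit0$bootstrap_samples <- est
  fit0$ci95 <- unname(stats::quantile(est, c(0.025, 0.975)))
  # a zero-width bootstrap distribution still has to contain the estimate
  fit0$ci95[1] <- min(fit0$ci95[1], fit0$estimate)
  fit0$ci95[2] <- max(fit0$ci95[2], fit0$estimate)
  fit0$fixed_inputs$vmax_ratio_ci <- vmax_ratio_ci
  fit0$fixed_inputs$iterations <- iterations
  fit0$fixed_inputs$seed <- as.integer(seed)
  fit0$fixed_inputs$resample_observations <- resample_observations
  fit0$fixed_inputs$vary_vmax <- vary_vmax
  fit0
}
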