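#' Weighted summary of a gliding-speed sample
#'
#' Weighted mean and SD of filament speeds using frequency weights (frames
#' tracked per filament).  When the sample carries biological-replicate
#' labels, a 95% confidence interval is computed from the per-replicate
#' weighted means with a t quantile on `n_replicates - 1` degrees of freedom;
#' otherwise `ci95_halfwidth` is `NA`.
#'
#' @param sample a [speed_sample()].
#' @return object of class `speed_summary`: list with `mean`, `sd`,
#'   `ci95_halfwidth`, `n` (filaments), `n_replicates`, `label`.
#' @export
velocity_summary <- function(sample) {
  if (!inherits(sample, "speed_sample"))
    abort_validation("`sample` must be a speed_sample")
  m <- weighted_moments(sample$speeds, sample$weights)
  ci <- NA_real_
  n_rep <- NA_integer_
  if (!is.null(sample$replicate)) {
    reps <- split(seq_along(sample$speeds), sample$replicate)
    n_rep <- length(reps)
    if (n_rep >= 2) {
      rm <- vapply(reps, function(i)
        weighted_moments(sample$speeds[i], sample$weights[i])$mean, numeric(1))
      ci <- stats::qt(0.975, n_rep - 1) * stats::sd(rm) / sqrt(n_rep)
    }
  }
  structure(list(mean = m$mean, sd = m$sd, ci95_halfwidth = ci,
                 n = length(sample$speeds), n_replicates = n_rep,
                 label = sample$label),
            class = "speed_summary")
}

#' @export
print.speed_summary <- function(x, ...) {
  cat(sprintf("<speed_summary> %s: %.3g +/- %.2g um/s (SD), n = %d filaments",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$mean, x$sd, x$n))
  if (is.finite(x$ci95_halfwidth))
    cat(sprintf("; 95%% CI halfwidth %.2g (N = %d replicates)",
                x$ci95_halfwidth, x$n_replicates))
  cat("\n")
  invisible(x)
}

#' Compare two gliding-speed samples with an unpaired two-tailed t test
#'
#' Welch's unequal-variance t test by default (`pooled = TRUE` gives the
#' classic pooled test).  When both samples carry replicate labels the test
#' runs on per-replicate weighted means, which is the honest experimental
#' unit; otherwise it runs on the raw per-filament speeds.
#'
#' @param a,b [speed_sample()] objects.
#' @param pooled use the pooled-variance test instead of Welch.
#' @return list with `t`, `p_value`, `df`, and `unit`
#'   (`"replicate"` or `"filament"`).
#' @export
compare_speeds <- function(a, b, pooled = FALSE) {
  for (s in list(a, b))
    if (!inherits(s, "speed_sample"))
      abort_validation("inputs must be speed_sample objects")
  rep_means <- function(s) {
    if (is.null(s$replicate)) return(NULL)
    vapply(split(seq_along(s$speeds), s$replicate), function(i)
      weighted_moments(s$speeds[i], s$weights[i])$mean, numeric(1))
  }
  xa <- rep_means(a)
  xb <- rep_means(b)
  unit <- "replicate"
  if (is.null(xa) || is.null(xb) || length(xa) < 2 || length(xb) < 2) {
    xa <- a$speeds
    xb <- b$speeds
    unit <- "filament"
  }
  if (length(xa) < 2 || length(xb) < 2)
    abort_validation("each sample needs n >= 2 to compare")
  tt <- stats::t.test(xa, xb, var.equal = pooled)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), unit = unit)
}

#' Combine independent uncertainties in quadrature
#'
#' @param uncertainties numeric vector of nonnegative uncertainties.
#' @return `sqrt(sum(uncertainties^2))`.
#' @examples combine_in_quadrature(c(3, 4))  # 5
#' @export
combine_in_quadrature <- function(uncertainties) {
  if (!is.numeric(uncertainties) || length(uncertainties) < 1L ||
      anyNA(uncertainties))
    abort_validation("`uncertainties` must be non-empty numeric without NA")
  if (any(uncertainties < 0))
    abort_validation("uncertainties must be >= 0")
  sqrt(sum(uncertainties^2))
}

#' Percent decrease of a test value relative to a reference
#'
#' @param reference reference value, > 0.
#' @param test test value.
#' @return `100 * (reference - test) / reference`.
#' @examples percent_decrease(1.69, 0.62)  # ~63.3
#' @export
percent_decrease <- function(reference, test) {
  assert_scalar_number(reference, "reference", positive = TRUE)
  assert_scalar_number(test, "test")
  100 * (reference - test) / reference
}

#' Optimum of a motor-loading curve
#'
#' Finds the loading concentration at which mean gliding speed is maximal.
#' Speeds are smoothed with a 3-point moving average (shrinking to the
#' available window at the ends) before taking the argmax; ties break toward
#' the lower concentration.  A strictly increasing curve returns the highest
#' concentration tested, flagged `"unsaturated"`.
#'
#' @param concentrations loading concentrations, ug/ml (>= 3 values).
#' @param speeds mean gliding speed at each concentration, um/s.
#' @param smooth apply the 3-point moving average (default TRUE).
#' @return list with `concentration`, `speed` (unsmoothed speed at the
#'   optimum), and `flag` (`"ok"` or `"unsaturated"`).
#' @export
optimum_loading <- function(concentrations, speeds, smooth = TRUE) {
  if (length(concentrations) < 3L || length(speeds) != length(concentrations))
    abort_validation("need >= 3 (concentration, speed) pairs")
  o <- order(concentrations)
  conc <- concentrations[o]
  sp <- speeds[o]
  sm <- sp
  if (smooth && length(sp) >= 3) {
    n <- length(sp)
    sm <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
      mean(sp[lo:hi])
    }, numeric(1))
  }
  i <- which.max(sm)  # which.max already breaks ties toward the first = lower conc
  flag <- if (all(diff(sp) > 0)) "unsaturated" else "ok"
  list(concentration = conc[i], speed = sp[i], flag = flag)
}

#' Map an immunoEM distance along the myosin rod to a residue position
#'
#' The myosin rod is a continuous coiled coil, so distance along the rod maps
#' linearly onto residue number: `residue = distance / rod_length *
#' rod_residues`.  An optional distance SD is propagated by the same scale
#' factor.  Defaults describe a 155 nm rod of 1096 residues per chain.
#'
#' @param distance_nm distance from the head-rod junction, nm, in
#'   `[0, rod_length]`.
#' @param rod_length_nm rod contour length, nm (default 155).
#' @param rod_residues residues per chain in the rod (default 1096).
#' @param distance_sd_nm optional SD of the distance measurement, nm.
#' @return list with `residue` and `residue_sd` (NA if no SD given).
#' @examples
#' map_rod_distance_to_residue(44)  # ~311 residues
#' @export
map_rod_distance_to_residue <- function(distance_nm, rod_length_nm = 155,
                                        rod_residues = 1096,
                                        distance_sd_nm = NULL) {
  assert_scalar_number(rod_length_nm, "rod_length_nm", positive = TRUE)
  assert_scalar_number(rod_residues, "rod_residues", positive = TRUE)
  assert_scalar_number(distance_nm, "distance_nm")
  if (distance_nm < 0 || distance_nm > rod_length_nm)
    abort_validation("distance %g nm lies outside the rod [0, %g]",
                     distance_nm, rod_length_nm)
  scale <- rod_residues / rod_length_nm
  sd <- NA_real_
  if (!is.null(distance_sd_nm)) {
    assert_scalar_number(distance_sd_nm, "distance_sd_nm", nonneg = TRUE)
    sd <- distance_sd_nm * scale
  }
  list(residue = distance_nm * scale, residue_sd = sd)
}
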