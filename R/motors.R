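#' Define a myosin species for the mixed-motor model
#'
#' A motor species is described by its unloaded gliding velocity `vmax`
#' (the speed actin glides over a surface of that motor alone, um/s) and the
#' dimensionless curvature `a/F0` of its hyperbolic (Hill) force-velocity
#' relation.  Smaller curvature values give more concave force-velocity
#' curves.  Curvatures are treated as fixed, muscle-derived constants: 0.25
#' for fast skeletal muscle myosin and 0.17 for cardiac myosin are the values
#' used throughout the package examples.
#'
#' @param name character label, e.g. `"WT-cHMM"`.
#' @param vmax unloaded gliding velocity, um/s; must be > 0.
#' @param curvature dimensionless Hill curvature a/F0, in (0, 1).
#' @return An object of class `motor_species`.
#' @examples
#' wt <- motor_species("WT-cHMM", vmax = 1.69, curvature = 0.17)
#' sk <- motor_species("Sk-myosin", vmax = 6.57, curvature = 0.25)
#' @export
motor_species <- function(name, vmax, curvature) {
  if (!is.character(name) || length(name) != 1L)
    abort_validation("`name` must be a single string")
  assert_scalar_number(vmax, "vmax", positive = TRUE)
  assert_scalar_number(curvature, "curvature")
  if (curvature <= 0 || curvature >= 1)
    abort_validation("`curvature` (a/F0) must lie in (0, 1); got %g", curvature)
  structure(list(name = name, vmax = vmax, curvature = curvature),
            class = "motor_species")
}

#' @export
print.motor_species <- function(x, ...) {
  cat(sprintf("<motor_species> %s: vmax = %.3g um/s, a/F0 = %.3g\n",
              x$name, x$vmax, x$curvature))
  invisible(x)
}

#' Pair a slow and a fast motor species with a force ratio
#'
#' The pair fixes everything the mechanical-interaction model needs except
#' the mole fraction: the two unloaded velocities, the two force-velocity
#' curvatures, and the ratio `F0s/F0f` of the unitary force of the slow
#' species to that of the fast species.
#'
#' @param slow,fast [motor_species()] objects; `slow$vmax` must not exceed
#'   `fast$vmax` (that is what "slow" and "fast" mean here).
#' @param force_ratio dimensionless `F0s/F0f` > 0.
#' @return An object of class `mixture_pair`.
#' @examples
#' pair <- mixture_pair(
#'   motor_species("WT-cHMM", 1.69, 0.17),
#'   motor_species("Sk-myosin", 6.57, 0.25),
#'   force_ratio = 3.3
#' )
#' @export
mixture_pair <- function(slow, fast, force_ratio = 1) {
  if (!inherits(slow, "motor_species") || !inherits(fast, "motor_species"))
    abort_validation("`slow` and `fast` must be motor_species objects")
  if (slow$vmax > fast$vmax)
    abort_validation("slow.vmax (%g) exceeds fast.vmax (%g): swap the species",
                     slow$vmax, fast$vmax)
  assert_scalar_number(force_ratio, "force_ratio", positive = TRUE)
  structure(list(slow = slow, fast = fast, force_ratio = force_ratio),
            class = "mixture_pair")
}

#' @export
print.mixture_pair <- function(x, ...) {
  cat(sprintf("<mixture_pair> %s / %s, F0s/F0f = %.3g\n",
              x$slow$name, x$fast$name, x$force_ratio))
  cat(sprintf("  slow: vmax %.3g um/s, a/F0 %.3g | fast: vmax %.3g um/s, a/F0 %.3g\n",
              x$slow$vmax, x$slow$curvature, x$fast$vmax, x$fast$curvature))
  invisible(x)
}
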