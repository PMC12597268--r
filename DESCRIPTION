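Package: myomech
Title: Mixed-Motor Motility Models and Three-Bead Optical Trap Analysis for Myosin Mechanochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative myosin motor mechanochemistry. Implements the
    Harris-Warshaw mechanical-interaction model for actin filaments gliding over
    mixtures of two myosin species (forward quadratic solver, inverse fitting of
    the slow/fast force ratio, bootstrap confidence intervals), a single-molecule
    three-bead optical trap pipeline (windowed bead-bead covariance, hysteresis
    event detection with changepoint boundary refinement, attachment-duration
    kinetics by truncated-exponential maximum likelihood, forward/reverse ensemble
    averages and two-substep power-stroke measurement), gliding-filament motility
    statistics (weighted velocity summaries, Welch comparisons, quadrature error
    propagation, loading-curve optimum, rod-distance to residue mapping), and
    seeded stochastic generators for trap recordings, dwell times, mixture
    datasets and gliding speeds so every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
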