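---
title: "Models and methods in myomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in myomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myomech)
```

`myomech` implements two quantitative pipelines from single-molecule and
ensemble myosin mechanochemistry — the mixed-motor mechanical-interaction
model for gliding assays, and a three-bead optical-trap analysis chain — plus
the seeded stochastic generators needed to test both without raw recordings.
This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data tests do and do
not establish.

## 1. The mixed-motor mechanical-interaction model

In a gliding assay over a mixture of a slow and a fast myosin, each motor
follows a hyperbolic (Hill) force-velocity relation characterized by its
unloaded velocity $V_{max}$ and the dimensionless curvature $a/F_0$.  Writing
$c_s = a_s/F_{0s}$, $c_f = a_f/F_{0f}$ and the force ratio $R = F_{0s}/F_{0f}$,
the force carried by one motor moving at velocity $V$ is
$F(V) = F_0\, c\,(V_{max} - V)/(V + c\,V_{max})$.  With mole fraction $k$ of
the fast motor, setting the net force on the filament to zero,

$$k\,c_f (V_f - V)(V + c_s V_s) + (1-k)\,R\,c_s (V_s - V)(V + c_f V_f) = 0,$$

which expands to the quadratic $A_1 V^2 + A_2 V + A_3 = 0$ with

$$A_1 = -c_s R (1-k) - k c_f,\qquad
  A_3 = c_s c_f V_s V_f\,[(1-k)R + k],$$
$$A_2 = c_s R (1-k)(V_s - c_f V_f) + k c_f (V_f - c_s V_s).$$

For any valid parameters and $k \in [0,1]$, $A_1 < 0$ and $A_3 > 0$, so the
product of the roots is negative and exactly one root is positive.
`solve_mixture_velocity()` evaluates it in closed form and asserts positivity
rather than trusting a formula branch.  The boundary roots are analytic
($V(0) = V_s$, $V(1) = V_f$) and tested to $10^{-9}$ relative error; an
independent bisection root-finder serves as the oracle in the test suite.

**Curvatures are fixed, not fitted.**  Following standard practice for this
assay, $a_f/F_{0f} = 0.25$ (fast skeletal muscle) and $a_s/F_{0s} = 0.17$
(cardiac muscle) are inputs; the only free parameter of
`fit_force_ratio()` is $R$.

**Fitting.**  The objective is the inverse-variance-weighted sum of squared
residuals between observed mean velocities and the model curve (unweighted
when no uncertainties are supplied — replicate counts differ across mole
fractions, so weights matter when available).  $R$ is located on a 60-point
log-spaced grid over $[0.05, 20]$ — which brackets every reported ratio
(0.8–3.3) with wide margin — then refined by bounded one-dimensional
minimization.  A dataset in which all velocities agree while the two
$V_{max}$ differ is flagged degenerate (warning, estimate still returned).

**Bootstrap.**  The published protocol derives the 95% CI by refitting 1000
times while "randomly varying" the $V_{max,s}/V_{max,f}$ ratio within its
95% CI.  Three gaps are closed as explicit design choices, all exposed as
arguments:

* *Sampling law*: uniform on the CI — the maximally agnostic distribution on
  a stated interval.
* *What is rescaled*: `slow$vmax` varies, `fast$vmax` is held; the slow
  species' speed carries the larger relative uncertainty in the motivating
  data.  `vary_vmax = "fast"` inverts this.
* *Observation resampling*: the protocol's footnote varies only the ratio
  ("footnote-strict", the default).  `resample_observations = TRUE`
  additionally case-resamples observations within each mole fraction so the
  CI also reflects data scatter; the coverage property test uses this mode,
  since a CI blind to data noise cannot promise nominal coverage on noisy
  synthetic data.

## 2. Three-bead trap pipeline

The recorded observables are two bead-position series of a trapped actin
dumbbell over a single myosin.  The analysis chain is: windowed bead–bead
covariance → hysteresis event detection → changepoint boundary refinement →
attachment-duration kinetics, forward/reverse ensemble averages, two-substep
measurement.

### 2.1 Covariance detection and why the window is 10 ms

Binding attenuates the correlated dumbbell fluctuation, so the windowed
covariance drops from $\sigma_c^2$ (unbound) to $\alpha^2 \sigma_c^2$
(bound attenuation $\alpha$).  The covariance estimator over a window of
$N$ samples with shared-noise autocorrelation $\rho = e^{-\Delta t/\tau}$
has variance approximately

$$\mathrm{Var}(\hat C) \approx \frac{1}{N}\Big[(\sigma_c^2 + \sigma_e^2)^2 +
  \sigma_c^4 + 2\sigma_c^4 \frac{\rho^2}{1 - \rho^2}\Big].$$

At the generator defaults ($\sigma_c = 5$ nm, $\sigma_e = 2$ nm,
$\tau = 0.5$ ms, 20 kHz) this gives an estimator SD of ≈11 nm² for a 5 ms
window against a bound/unbound contrast of 25 → 2.25 nm²: single-window
discrimination is hopeless, and false events overwhelm the precision budget.
A 10 ms window (SD ≈ 8 nm²) with hysteresis thresholds from a two-component
Gaussian mixture (`auto_thresholds()`: open below $\mu_b + \sigma_b$, close
above $\mu_u - \sigma_u$) and a minimum duration of two windows (20 ms)
yields ≥90% recall and ≥90% precision at the default SNR.  All three
parameters are arguments of `analyze_trap_recording()`.

The mixture EM is initialized deterministically from the 2% and 60%
quantiles (the bound mode can hold well under 10% of windows); if the two
modes fail to separate by the sum of their SDs the function falls back to
the 30%/70% quantile span with a warning.

### 2.2 Boundary refinement

Hysteresis boundaries are only window-accurate, and they are *late* by
construction (the covariance falls only once most of a window is bound).
`refine_events()` re-estimates each boundary as a Gaussian changepoint —
both the mean (the power stroke) and the variance (the attenuation) change
at binding — on the mean bead position, searching an asymmetric window
(24 ms before / 6 ms after the coarse start; 20 / 8 ms around the coarse
end).  Residual start jitter is ≈0.2 ± 1.3 ms with ~2% outliers (quick
rebinds after detachment can merge two true events; the changepoint then has
no single true answer).

### 2.3 Ensemble averages and rate fits

Events are aligned at their (refined) start or end, baseline-subtracted
(10 ms pre-event window ending 5 ms before the start — a 2 ms gap would leak
attached samples whenever the start is refined late), and averaged.  Events
shorter than the span are extended by holding their final (forward) or
initial (reverse) attached level, which keeps per-bin counts constant and
makes the expected averages exactly

$$\bar y_{fwd}(t) = s_1 + s_2\,(1 - e^{-k_1 t}),\qquad
  \bar y_{rev}(t) = s_1 + s_2\,e^{-k_2 |t|},$$

the forms fitted by `fit_ensemble_rates()`.  Three numerical details:

* The held level is measured over 8 ms (with a 1 ms end guard) on the
  forward side: each held event contributes one constant to *every* later
  bin, so hold-level noise is the dominant correlated noise in the plateau
  and shrinks with the window.  The reverse hold (the state-1 level) is
  capped at 2 ms because the state-1 dwell itself is only ~16 ms.
* Bins closer than `guard_s` (5 ms) to the alignment point are excluded from
  the fits: boundary jitter contaminates them, and a time shift leaves both
  exponential rates unchanged (it only rescales the amplitude), so the guard
  costs amplitude, not accuracy.
* Fits are weighted by the per-bin variance of the mean
  ($n/\mathrm{sd}^2$, capped at 3× the median weight because held bins
  repeat one noisy constant and overstate their information), run through
  `nls(port)` and polished by a derivative-free pass; "false convergence" on
  these flat weighted surfaces is routine and rescued, while genuinely
  non-convergent or amplitude-free fits are returned flagged, never silently
  replaced.

### 2.4 Substeps

Per event: `substep1` = mean over a 2 ms window at the start minus baseline;
`total` = mean over a 5 ms window ending 1 ms before the end minus baseline;
`substep2 = total − substep1`.  The early window is deliberately *short*: a
window of width $w$ overlaps the state-1→2 transition with probability
$\approx k_1 w$, biasing substep 1 upward by
$s_2\,[1 - (1 - e^{-k_1 w})/(k_1 w)]$ — already ≈0.07 nm at $w = 2$ ms and
≈0.16 nm at 5 ms.  With sub-millisecond refined-start jitter no start guard
is needed; the end guard is cheap because the state-2 dwell is long.  The
residual bias of the substep-2 mean at the default rates is ≈−0.12 nm,
within the 0.3 nm acceptance band; events too short for both windows are
excluded from substep 2 and counted.

### 2.5 Attachment durations

`fit_exponential_rate()` is the maximum-likelihood estimator for a
left-truncated exponential, $\hat k = 1/(\overline d - d_{min})$: the
detector cannot see events shorter than its minimum duration, and for an
exponential the excess over the truncation point is again exponential.  A
least-squares fit of the cumulative distribution is reported alongside
(`details$cdf_rate`); the MLE is primary because its small-sample bias
($\sim k/n$) is known and tested (<2% at $n = 500$).  Note the two-state
event structure makes true durations hypoexponential, not exponential; the
single-exponential rate is the standard summary and is reported as such,
without forcing consistency with the two ensemble rates (their printed
values in the motivating study are likewise mutually inconsistent:
$1/(1/63.1 + 1/4.94) \approx 4.6 \ne 5.9$ s⁻¹).

## 3. The synthetic generators: what they emulate, what they omit

`simulate_trap_recording()` produces: a shared dumbbell fluctuation as an
exact-discretization Ornstein–Uhlenbeck process (autoregression
$e^{-\Delta t/\tau}$, so the stationary variance is analytic and testable),
independent white noise per bead, Poisson event arrivals (arrivals during an
event are discarded — the single-molecule condition), a two-state bound
period (substep 1 at attachment, substep 2 after an exponential state-1
dwell, detachment after an exponential state-2 dwell), and covariance
attenuation while bound.  Defaults are the published operating point:
20 kHz sampling, substeps 4.03 and 1.10 nm, $k_1 = 63.1$ s⁻¹,
$k_2 = 4.94$ s⁻¹ (alternatively derived as $4.6\ \mu M^{-1}s^{-1} \times
[ATP]$), 1 μM ATP.  Noise parameters (shared SD 5 nm, independent SD 2 nm,
$\tau = 0.5$ ms, attenuation 0.3, arrivals 0.5 s⁻¹) are not published
quantities; they were chosen once as a realistic operating point at which
the printed rates and substeps are recoverable at the printed event count
(516), and are not tuned per test.

Deliberately **not** modeled: trap-stiffness calibration, the full
bead–actin–bead compliance chain (both beads report the motor displacement
identically), event-to-event step-size variability (measured step
histograms get their spread from thermal noise only), instrument drift, and
negative-polarity events.  A green recovery test therefore establishes that
the *analysis chain* is unbiased at realistic SNR — not that it is robust
to compliance artifacts or drifting baselines in real recordings.

Mixture datasets are the forward model times $(1 + \varepsilon)$,
$\varepsilon \sim N(0, cv)$ truncated at zero, with 6 mole fractions ×
3 technical replicates and $cv = 0.05$ as the stated experimental scale;
gliding speeds are zero-truncated normal with unit weights.

## 4. Motility statistics

* Weighted summaries treat weights as frequency weights (frames tracked per
  filament); equal weights reduce to the unweighted mean and all summaries
  are invariant under weight rescaling.
* `compare_speeds()` defaults to Welch's unequal-variance two-tailed t test
  (`pooled = TRUE` for the classic test) and runs on per-replicate means
  when replicate labels exist — the biological replicate, not the filament,
  is the honest experimental unit.
* `optimum_loading()` smooths with a 3-point moving average before the
  argmax (curves in loading assays are illustrative, not model fits), breaks
  ties toward the lower concentration, and flags strictly increasing curves
  "unsaturated".
* `map_rod_distance_to_residue()` is the linear map
  $\mathrm{residue} = d/155\,\mathrm{nm} \times 1096$; 44 nm gives 311.2,
  one residue below the rounded published 312 (the original rounding inputs
  are unstated; the linear map is authoritative here).  The published
  ±28-residue uncertainty corresponds to a ≈4 nm distance SD, which is an
  explicit optional input, never assumed.

## 5. Known limitations

* The covariance detector merges binding events separated by less than
  roughly one covariance window (~1% of events at the default arrival
  rate), and misses events shorter than the 20 ms minimum duration (~4% at
  the default rates); both limits are properties of any covariance-threshold
  scheme at this SNR.
* The forward-ensemble rate $k_1$ is the noisiest recovered quantity
  (per-recording SD ≈ 15% at ~250 events, ≈ 10% at the published 516);
  the 15% acceptance band is adequate but not generous.
* The bootstrap CI in footnote-strict mode reflects only $V_{max}$-ratio
  uncertainty, by design; use `resample_observations = TRUE` when the CI
  must also cover data scatter.
* CLI configuration files are JSON (no YAML parser among the package's
  dependencies).
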