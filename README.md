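# myomech

Quantitative tools for myosin motor mechanochemistry in R.  The package is
aimed at single-molecule and motility-assay labs that need reproducible,
tested implementations of two standard analyses:

1. **Mixed-motor gliding model.**  When actin glides over a surface carrying
   a mixture of a slow and a fast myosin, the steady-state velocity deviates
   from linear mixing in a way that encodes the *force ratio*
   `R = F0s/F0f` of the two motors.  With Hill force–velocity curvatures
   `cs = as/F0s`, `cf = af/F0f` (fixed at the muscle-derived values 0.17 and
   0.25 for cardiac and fast skeletal myosin), unloaded velocities `Vs`,
   `Vf`, and fast-motor mole fraction `k`, the velocity is the unique
   positive root of

   ```
   A1 V^2 + A2 V + A3 = 0
   A1 = -cs R (1-k) - k cf
   A2 = cs R (1-k)(Vs - cf Vf) + k cf (Vf - cs Vs)
   A3 = cs cf Vs Vf [(1-k) R + k]
   ```

   The package provides the forward solver, weighted inverse fitting of `R`,
   and the bootstrap CI protocol that perturbs the `Vmax` ratio within its
   95% CI (1000 iterations).

2. **Three-bead optical trap pipeline.**  Actomyosin binding events of a
   trapped actin dumbbell are detected as drops in windowed bead–bead
   covariance (hysteresis thresholds from a Gaussian-mixture fit), refined
   to sample resolution by changepoint analysis, and summarized as: the
   attachment-duration rate `k_detach` (left-truncated exponential MLE),
   forward/reverse ensemble averages fit to `s1 + s2(1 - exp(-k1 t))` and
   `s1 + s2 exp(-k2 |t|)` (the two-substep power stroke: substep 1 with
   phosphate release, substep 2 with ADP release, detachment on ATP
   binding), and per-event substep-size tables.

Seeded generators (`simulate_trap_recording()`, `simulate_mixture_dataset()`,
`simulate_durations()`, `simulate_gliding_speeds()`) produce synthetic data
with the statistical structure the analyses assume, so the whole chain is
testable end to end without raw recordings.  Gliding-assay statistics
(weighted velocity summaries, Welch comparisons, quadrature error
propagation, loading-curve optima, rod-distance→residue mapping) round out
the package.

## Worked example: force ratio of a slow/fast myosin pair

```r
library(myomech)

wt <- motor_species("WT-cHMM",  vmax = 1.69, curvature = 0.17)
sk <- motor_species("Sk-myosin", vmax = 6.57, curvature = 0.25)

# forward model at the fitted force ratio 3.3
pair <- mixture_pair(wt, sk, force_ratio = 3.3)
predict_curve(pair, c(0, 0.25, 0.5, 0.75, 1))

# synthetic mixture dataset (5% CV, 3 replicates) and inverse fit
d   <- simulate_mixture_dataset(pair, seq(0, 1, length.out = 6),
                                noise_cv = 0.05, replicates = 3, seed = 1)
fit <- bootstrap_force_ratio(d, wt, sk,
                             vmax_ratio_ci = (1.69 / 6.57) * c(0.94, 1.06),
                             iterations = 1000, seed = 1)
fit
```

```
#>      k velocity_um_s
#> 1 0.00      1.690000
#> 2 0.25      2.113147
#> 3 0.50      2.848065
#> 4 0.75      4.159699
#> 5 1.00      6.570000
#> <force_ratio_fit> F0s/F0f = 3.29  (95% CI 3.07 - 3.54, 1000 bootstrap iterations)
#>   objective (weighted SSR): 0.5598
```

The curve is concave: at equal mole fractions the mixture glides at
2.85 um/s, far below the 4.13 um/s linear-mixing value, because the slow
motor is ~3-fold stronger and brakes the fast one.  The fit recovers the
generating ratio 3.3 within noise, and the bootstrap CI brackets it.

## Worked example: synthetic trap recording

```r
rec <- simulate_trap_recording(trap_sim_params(duration_s = 120, seed = 42))
an  <- analyze_trap_recording(rec)
an
```

```
#> <trap_analysis> 46 events
#>   k_detach (duration MLE): 4.47 +/- 0.66 s^-1
#>   k1 (forward ensemble): 73.63 s^-1 [ok]
#>   k2 (reverse ensemble): 6.386 s^-1 [ok]
#>   substeps: 3.81 nm + 0.868 nm (n = 45)
```

46 events is a short recording; at the published event count (516, pooled
across recordings with `trap_recovery_study()`) the two ensemble rates land
within 15% of the generating 63.1 and 4.94 s^-1 and both substep means
within 0.3 nm of the generating 4.03 and 1.10 nm.

## Command line

Six subcommands wrap the stages into reproducible runs with JSON manifests:

```sh
Rscript -e 'quit(status = myomech::myomech_cli())' \
  simulate-mixture --seed 7 --out-dir out --set force_ratio=3.3
Rscript -e 'quit(status = myomech::myomech_cli())' \
  fit-mixture --seed 7 --out-dir out --set input=out/mixture.tsv \
  --set vmax_slow=1.69 --set vmax_fast=6.57
```

Subcommands: `simulate-trap`, `analyze-trap`, `simulate-mixture`,
`fit-mixture`, `gliding-stats`, `rod-map`.  Flags: `--seed`, `--out-dir`,
`--verbose`, `--config <json>`, repeated `--set key=value`.

## Documentation

The methods vignette (`vignettes/myomech-methods.Rmd`) documents the models,
every tunable parameter with its default and rationale, the numerical
choices (detection window sizes, boundary refinement, guards, truncated
MLE), and what the synthetic-data tests do and do not establish.
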