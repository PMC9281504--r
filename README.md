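# pushrim

Kinetic and spatio-temporal analysis of manual wheelchair propulsion from
instrumented handrim wheels (SmartWheel-style recordings), built for
studies that compare propulsion *with and without a hand-held implement* —
the motivating case is Para badminton, where one hand grips both the
handrim and a racket.

The package takes raw per-wheel time series (forces `Fx, Fy, Fz`, moments
`Mx, My, Mz`, cumulative wheel angle `θ`, sampled at 240 Hz) through the
complete pipeline used in instrumented-wheel studies:

1. **Offset correction** — angle-dependent sensor offsets modelled as
   `c0 + a·sin θ + b·cos θ` per channel, fitted on coasting (non-contact)
   samples and subtracted.
2. **Velocity** — wheel angular velocity `θ̇` via a 131-point first-order
   Savitzky–Golay derivative filter; linear velocity `v = θ̇·r_wheel`.
3. **Push segmentation** — hand-contact phases are maximal runs with total
   force `Ftot = √(Fx² + Fy² + Fz²) ≥ 30 N`, debounced; the first two and
   last pushes of a run are excluded as transitional; manual review is a
   reproducible edit-directive API with an audit log.
4. **Per-push parameters** (per push, then averaged per trial and side):

   | parameter | definition |
   |---|---|
   | `ftot_peak` [N] | max `Ftot` |
   | `mz_peak` [N·m] | max propulsive moment |
   | `ror` [N/s] | rate of rise, max d`Ftot`/dt in push |
   | `fef` [%] | fraction of effective force, time-average of \|F_tan/F_tot\|·100 with `F_tan = Mz / r_handrim` |
   | `po_peak` [W] | max `θ̇ · Mz` |
   | `ai` [N·m·s] | angular impulse, mean `Mz` × push time |
   | `pt` [s] | push (contact) time |
   | `ct` [s] | cycle time, start-to-start |
   | `pa` [°] | wheel angle traversed during contact |

5. **Statistics** — the within-subject 2×2 comparison (condition
   with/without racket × dominant/non-dominant hand): natural-log
   transform, Shapiro–Wilk screen, repeated-measures ANOVA with partial
   eta-squared `η²p = SS_effect / (SS_effect + SS_error)` (Greenhouse–
   Geisser ε = 1 for two-level factors), paired t tests with Bonferroni
   adjustment, and pooled-SD Cohen's d
   `d = |m0 − m1| / √((s0² + s1²)/2)` computed from the untransformed
   cell means/SDs — the form that reproduces published comparison tables
   from their own printed summaries.

A synthetic-signal generator (`generate_trial()`, `generate_study()`)
produces SmartWheel-like trials from half-sine push profiles with full
closed-form ground truth, so every stage is testable end to end without
any recorded data.

## Worked example

Simulate one paced trial (1.4 m/s, eight pushes, 2 N sensor noise),
analyze it, and inspect the trial summary:

```r
library(pushrim)

gen <- generate_trial(trial_recipe(seed = 8))
res <- analyze_trial(gen$ts)
res$summary
#>   side  n_analyzed velocity ftot_peak mz_peak   ror   fef po_peak    ai    pt
#> 1 right          5     1.40      99.9    9.21  840.  34.5    39.1  2.00 0.288
#>      ct    pa
#>  1 1.19  68.8
```

Five pushes survive transitional exclusion; the recovered peak force
(≈100 N), effectiveness (≈35%, the injected tangential fraction) and pace
(1.40 m/s) match the recipe. `plot_pushes(gen$ts, res$pushes)` shows the
force trace with the detected contact phases shaded.

A full 2×2 study with the racket-effect pattern injected
(`racket_effects()`: the racket-bearing dominant hand pushes harder but
less effectively, and the cycle quickens):

```r
st  <- generate_study(n_participants = 16, effects = racket_effects(), seed = 2)
rep <- compare_panels(study_summaries(st))
format_report(rep)$unilateral
#>  parameter with_mean with_sd without_mean without_sd statistic p_raw p_adjusted     d      d_band
#>  ftot_peak    170.71   48.86       125.55      36.78    37.024 0.000          0 1.044       large
#>    mz_peak     12.07    3.86        10.86       3.37     9.129 0.000          0 0.335       small
#>        ror   1634.45  520.26      1120.87     377.06    37.349 0.000          0 1.130       large
#>        fef     26.46    3.62        32.44       3.91   -25.699 0.000          0 1.587       large
#>    po_peak     51.17   16.36        46.03      14.29     9.129 0.000          0 0.335       small
#>         ai      2.46    0.78         2.30       0.73     5.152 0.000          0 0.208       small
#>         pt      0.29    0.03         0.29       0.03    -0.190 0.852          1 0.020 below_small
#>         ct      1.06    0.11         1.22       0.13   -16.356 0.000          0 1.327       large
#>         pa     69.71    6.58        69.85       6.98    -0.190 0.852          1 0.020 below_small
```

The dominant hand with the racket shows higher peak force and rate of
rise, lower fraction of effective force and shorter cycle time — the
qualitative pattern reported for racket-in-hand propulsion. `run_study()`
runs the same comparison from raw wheel recordings (a YAML manifest of
CSV files, or an in-memory synthetic study), and `write_study()` /
`read_manifest()` round-trip a study through disk.

`tidy()`, `glance()` and `autoplot()` methods are provided for fitted
ANOVAs and study reports.

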