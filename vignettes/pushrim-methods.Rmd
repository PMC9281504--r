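---
title: "Methods: pushrim kinetics from instrumented wheels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pushrim kinetics from instrumented wheels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pushrim)
```

## The measurement problem

Instrumented wheelchair wheels measure, at the handrim and at 240 Hz, the
three force components `Fx, Fy, Fz`, the three moments `Mx, My, Mz`, and
the cumulative wheel angle θ. From these, studies of propulsion derive a
standard panel of per-push parameters: how hard the athlete pushes
(`ftot_peak`, `mz_peak`), how abruptly (`ror`), how effectively (`fef`),
how powerfully (`po_peak`, `ai`), and with what timing (`pt`, `ct`,
`pa`). The scientific contrast this package is built around is a fully
within-subject 2×2 design: propulsion **with vs without a racket** held
on the **dominant vs non-dominant** hand, paced at 1.4 m/s over a 20 m
straight.

Only the resultant force and `Mz` enter any parameter, so the package
carries the per-axis convention (`Fy` vertical on the rim, `Fx` lateral,
`Fz` out of plane) without enforcing it; recordings that follow a
different axis convention produce identical results.

## Preprocessing

**Dynamic offsets.** Wheel-fixed force sensors see gravity rotate through
their frame, producing offsets that vary with wheel angle. The package
models each force/moment channel's offset as a constant plus first
harmonic, `c0 + a·sin θ + b·cos θ`, fitted by least squares on
non-contact samples and subtracted everywhere. This captures the
dominant, gravity-induced component of dynamic offsets; it is a
deliberate simplification of full dynamic-offset cancellation procedures
(which also model inertial terms), and the `offset_model` config key
exposes `none`, `constant` and `harmonic`. The non-contact mask comes
from a provisional 30 N segmentation of the *raw* total force, widened by
50 ms on each side, which avoids circularity with the final segmentation;
the fit requires at least 100 samples spanning a full wheel revolution so
the harmonic terms are identifiable.

**Velocity.** Wheel angular velocity is the Savitzky–Golay derivative of
θ with window 131 samples (≈ 0.55 s at 240 Hz) and polynomial order 1 — a
sliding local-slope estimator. "Order 1" is read literally: with a
two-level derivative this is the minimal filter consistent with the
phrase "first-order derivative filter", and both window and order are
config keys (`sg_window`, `sg_polyorder`). Edges are handled by
*point-symmetric (odd) reflection* about the end samples rather than the
usual even reflection or transient polynomial fits: odd reflection
continues a locally linear signal exactly, so a constant-velocity trial
has an exact derivative out to the first and last sample. Whether a study
should differentiate the left, right, or averaged wheel angle for
"wheelchair velocity" is under-determined; the package reports per-wheel
velocity and uses each trial's own wheel for pace verification
(`verify_pace()`, target 1.4 m/s, tolerance 0.1 m/s).

**Channel smoothing.** After offset removal, the six force/moment
channels pass through a Savitzky–Golay smoother (order 2, window 15 ≈
63 ms, `smooth_window`). This is the package's sensor-noise suppression
step. The window was chosen by an explicit error budget, not by eye: a
15-sample quadratic window attenuates white noise by a factor ≈ 2.6
while distorting a 0.35 s half-sine push peak by well under 0.5%, so peak
parameters gain an order of magnitude in precision at negligible bias.
`smooth_window = 0` disables the step.

## Segmentation

A push is a maximal run of samples with `Ftot ≥ 30 N` on the
offset-corrected total force. Two debouncing rules make the threshold
robust on real signals: below-threshold gaps shorter than 50 ms are
merged (`min_gap_s`), and surviving runs shorter than 100 ms are
discarded (`min_push_s`). Both are conservative relative to observed push
times (~0.34–0.37 s) and cycle times (~1.1–1.3 s) and are config-exposed;
the threshold source (corrected vs raw force) and the debounce rules are
documented assumptions, since published protocols typically state only
the threshold itself.

The first two and the last detected push of a run are transitional
(acceleration from standstill; final release) and are excluded from
analysis; at least four detected pushes are therefore required. The
"manual check" of automated segmentation is reproducible here:
`review_segmentation()` applies a list of add/remove/adjust directives,
re-validates disjointness, re-applies exclusion, and appends every
directive to an audit log.

`end_index` is inclusive, so push time is `(end − start + 1)/fs`; the
boundary convention is fixed and tested rather than left implicit.

## Parameter definitions and their open choices

Three parameters admit more than one reasonable reading; the package
implements the alternatives behind config switches and fixes a primary:

- **Rate of rise** is the maximum in-push time-derivative of `Ftot`
  (primary), not peak force divided by time-to-peak (available as
  `ror_variant = "peak_over_time"`). The derivative is a 5-point
  Savitzky–Golay filter (order 2) by default — essentially exact on
  clean signals — but the pipeline widens it to 15 samples
  (`ror_window`): at 240 Hz a 5-point derivative amplifies white noise
  by `fs·√(1/10) ≈ 76`, i.e. ≈ 150 N/s of derivative noise per 2 N of
  sensor noise, which would swamp the quantity being measured. The
  derivative is evaluated over the whole series, so windows near the
  push onset see the true below-threshold samples rather than padding.
- **Fraction of effective force** is the time-average over the push of
  the instantaneous `|F_tan/F_tot|` (primary), with `F_tan = Mz /
  r_handrim`; ratio-of-means and value-at-peak variants are available
  (`fef_variant`). Samples implying `F_tan > F_tot` raise a QC warning
  and are never clamped.
- **Peak power** is `max(θ̇ · Mz)`: a product of angle and moment only
  has watt units with the angular *velocity*, so the printed form
  "θ × Mz" is read as θ̇·Mz.

Braking pushes (negative peak moment) are flagged with a QC warning, not
dropped. Cycle time is undefined for the last analyzed push and excluded
from its trial mean.

## Statistics

All nine parameters are strictly positive and typically right-skewed, so
tests run on natural-log data (the base is irrelevant to any test). The
Shapiro–Wilk screen wraps the standard Royston approximation with typed
errors for degenerate input.

The 2×2 repeated-measures ANOVA partitions within-subject sums of
squares into condition, side, interaction, and the three
effect-by-subject error strata; each effect is tested against its own
stratum with `F = MS_effect / MS_(effect×subject)` and summarized by
partial eta-squared `SS_effect/(SS_effect + SS_error)`. With two levels
per factor, sphericity holds trivially and the Greenhouse–Geisser ε
equals 1 exactly; the correction is nevertheless carried and applied to
the degrees of freedom so the mechanics generalize. (Published 2×2
analyses sometimes report Mauchly's test as violated, which is not
well-defined for two-level factors; ε = 1 is used here and the
discrepancy is simply noted.) For a zero effect sum of squares the
package defines F = 0 and η²p = 0 even when the error stratum is also
empty.

**Effect sizes.** Cohen's d is computed from the *untransformed* group
means and SDs with the pooled denominator `√((s0² + s1²)/2)`. A
literal "divide by sd of the reference group" definition does not
reproduce published effect-size columns from their own printed means and
SDs, while the pooled form reproduces every one of them to the printed
precision (e.g. 31.24/42.14 = 0.741 for peak total force); the pooled
form is therefore primary and the reference-SD form sits behind
`d_variant = "reference"`. d is reported as an absolute value, matching
how comparison tables print it. Band labels follow Cohen's conventions
(d: 0.2/0.5/0.8; η²p: 0.01/0.06/0.14, thresholds inclusive).

**Multiplicity.** The Bonferroni family size defaults to 4 — the four
simple-effect cell contrasts of a 2×2 design — and is config-exposed
(`bonferroni_m`); raw and adjusted p values are both reported.

## The synthetic generator

`generate_trial()` synthesizes one wheel recording from a push profile:
half-sine total force `F·sin(π(t−t0)/PT)` per push, moment
`Mz = tf·Ftot·r_handrim` with constant tangential fraction `tf`, the
non-tangential force magnitude split 80/20 (by squared magnitude)
between in-plane radial and out-of-plane components, the in-plane force
rotated with the wheel angle, θ integrating a constant angular velocity,
then Gaussian sensor noise and optional angle-dependent offsets.
Everything is deterministic given the recipe seed, and summary-level
generation (`trial_truth_summary()`, `study_summaries()`) consumes the
same RNG draws as signal-level generation, so the two views of a trial
never diverge.

Default conditions emulate paced court-sport propulsion: peak force
100 N, tangential fraction 0.35 (FEF 35%), push time 0.35 s, cycle time
1.2 s, speed 1.4 m/s on a 26-inch wheel, 8 pushes per 20 m run, force
noise 2 N, moment noise 0.2 N·m (typical of commercial instrumented
wheels), per-push lognormal variability 0.05 (log scale) and
between-subject variability 0.25/0.12/0.08/0.08 for force, tangential
fraction and the two durations. Variability is multiplicative
(lognormal) throughout because all parameters are positive and the
statistics log-transform — the generator and the analysis assume the
same structure. The in-push speed ripple defaults to 0: a
cadence-frequency ripple is almost entirely attenuated by the 0.55 s
velocity filter, so modelling it would change nothing downstream; the
`speed_ripple` parameter exists for sensitivity work.

**Ground truth and the threshold.** Every parameter has a closed form
under the half-sine model (`ftot_peak = F`, `ror = πF/PT`,
`fef = 100·tf`, `ai = (2/π)F·tf·r·PT`, `po_peak = θ̇·tf·F·r`, `pt = PT`,
`ct = CT`, `pa = θ̇·PT·180/π`). A 30 N threshold, however, measures
slightly different quantities by construction: it trims the
sub-threshold tails of each half-sine, shortening a 100 N / 0.35 s push
by ≈ 19% of PT and the angular impulse by ≈ 4.6%. The ground truth
therefore carries both the nominal forms and threshold-consistent
"observed" forms (`pt_obs = PT(1 − 2·asin(thr/F)/π)`,
`ror_obs = (πF/PT)·√(1−(thr/F)²)`, analytic `ai_obs`, sample-exact
boundary indices). Closed-form metric checks evaluate the kinetics
functions on full half-sine intervals, where the nominal forms are
exact; pipeline recovery is judged against the observed forms, which are
what a thresholding pipeline genuinely measures.

**Cell effects.** `generate_study()` applies multiplicative
condition/side/interaction effects to the profile fields.
`racket_effects()` encodes the directional pattern published for
racket-in-hand propulsion — peak force multipliers 1.173 (condition),
1.173 (side), 1.160 (interaction); tangential-fraction multipliers
0.993/0.871/0.825; push time ×0.946 with the racket; cycle time ×0.875 —
derived from the published 2×2 cell means. One interaction of the
generator is worth knowing: because higher peaks lose proportionally
less of the half-sine to the threshold, the *observed* push time barely
changes under the racket effect even though the nominal push duration
shortens; the package's directional checks therefore use the robust
pattern (peak force and rate of rise up, effectiveness down, cycle time
down) rather than the marginal push-time contrast.

**What the generator does not emulate.** The tangential fraction is
constant within a push, so the peak moment and peak power are lower,
relative to peak force, than in published tables (real pushes
concentrate tangential force mid-push); braking moments, camber
mechanics, rolling resistance, starts from standstill and recovery-phase
hand dynamics are absent; noise is white and Gaussian. Passing
recovery tests on these signals validates the pipeline's numerics and
bookkeeping — threshold behaviour, filter bias, index conventions,
statistical calibration — not the physiological realism of any
particular signal shape.

## Validation sizes and numerical choices

The shipped checks use: 50 noisy trials (seeds drawn from the run seed)
for parameter recovery, judged at the trial-summary level — the unit the
statistics consume — with a ≤ 2% mean absolute relative error bound
(≤ 2 samples for push/cycle time); 100 random panels against a
brute-force sums-of-squares oracle at 1e-10 and `F = t²` at 1e-9; 2,000
null studies of 16 participants for type-I calibration (expected
rejection 0.035–0.065 at α = 0.05 per effect); and 100 racket-effect
studies for directional reproduction (≥ 95% agreement). These sizes keep
the full suite comfortably within a few minutes while leaving Monte
Carlo noise well below the tolerances being tested.

Numerical conventions collected in one place: odd-reflection padding for
all Savitzky–Golay filters; time sorting at load; NaN rejection rather
than interpolation (silent interpolation could fabricate pushes); zero
effect SS ⇒ zero F and η²p; sample-inclusive push intervals; report
rounding to 2 decimals for means/SDs and 3 for effect sizes, with full
precision retained in the report object.

## Limitations

The offset model omits inertial terms, so rapidly accelerating trials
would retain a residual dynamic offset. The pipeline is built for the
2×2 within-subject design; larger factorial designs would need a general
ε estimate, which is deliberately out of scope. Left wheels are handled
by a sign convention flag at I/O time; hardware with other conventions
needs the flag set in the manifest. The FEF derivation from `Mz /
r_handrim` attributes all moment to tangential hand force, the standard
instrumented-wheel assumption; gripping moments violate it equally for
all conditions being compared.
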