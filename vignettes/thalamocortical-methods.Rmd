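---
title: "Methods: thalamocortical regime charting and the white-matter statistics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thalamocortical regime charting and the white-matter statistics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling and statistical choices behind
`ictogen`: the neural mass model and its calibration, the regime
classifier, the frontier and concordance machinery, the threshold-grid
statistics, and what the synthetic-data generator does and does not
emulate.

## The model and its assumptions

The circuit has two cortical populations with saturating (sigmoid)
activation — pyramidal cells `PY` and inhibitory interneurons `IN` — and
two linear thalamic populations — relay cells `TC` and reticular nucleus
`RE`.  The sigmoid wraps the *whole* input of each cortical equation
(`a = 1`, `θ = 4`), while the thalamic equations are linear in their
inputs; white noise of amplitude `α`, scaled by `1/τ₃` and `√dt` per
Euler–Maruyama step, enters the `TC` equation only, standing for
non-specific ascending brain-stem input.  Whether that noise should be
scaled by `1/τ₃` is a genuine ambiguity; we divide by `τ₃`, consistent
with dividing the whole right-hand side by `τ₃`, and note that a
different convention only rescales `α`.

The model is a lumped, spatially unresolved caricature: one cortical
column, one thalamic sector, no conduction delays, no plasticity.  Its
purpose is qualitative — which *directions* in connectivity space
support seizure dynamics — not waveform fitting.

## Calibration of the default preset

The shipped parameters are an in-house calibration built by the
slow–fast recipe: first place the cortical pair (`PY`, `IN`) near the
oscillatory window of its drive, then couple the slow thalamic pair
(`τ₃ = τ₄ = 0.25` s against `τ₁ = 6` ms, `τ₂ = 12` ms) so that its
feedback can move the cortex across that window.  The healthy operating
point is the *high-activity* cortical fixed point, sitting just above
the top of a 20–30 Hz oscillatory band:

* reducing cortico-cortical `c₁` lowers the recurrent drive and drops
  the cortex into the band (fast oscillation) or, with strong slow
  feedback, into 2–4 Hz spike-wave bursting;
* raising cortico-reticular `c₈` strengthens the *negative* slow
  feedback loop `PY→RE⊣TC→PY`, with the same effect;
* raising `c₇` or `c₉` strengthens the *positive* thalamic feedback and
  protects the fixed point.

This is why the seizure frontier has a positive slope in the
`(c₁, c₈)` plane (seizure above) and negative slopes for `(c₁, c₇)` and
`(c₁, c₉)` — the geometry the concordance check consumes.  Time
constants were chosen last, to place the fast region's median frequency
in the 20–30 Hz band and the spike-wave fundamentals in the clinical
2–4.5 Hz range near the frontier.  All defaults live in
`inst/extdata/presets/default.yaml`; `bistable.yaml` (`c₁ = 13.5`,
`c₈ = 4.1`, `α = 0.2`) and `swd.yaml` (`c₁ = 13.5`, `c₈ = 5.2`) are
points of the same calibration chosen for attractor coexistence and for
a ~3 Hz monostable spike-wave rhythm respectively.

## Numerical integration

Deterministic solutions use an adaptive Dormand–Prince 5(4) scheme with
dense cubic-Hermite output on a uniform 500 Hz grid (relative tolerance
`1e-8`, absolute `1e-10`), implemented in C inside the package because a
plane scan integrates ~10⁴ short trajectories and per-solve overhead
dominates otherwise; `deSolve` serves as an independent oracle in the
test suite.  Stochastic solutions use fixed-step Euler–Maruyama at
`dt = 1/15000` s, recorded at the solver step and kept at 500 Hz; with
`α = 0` the scheme is exactly fixed-step Euler and converges to the
smooth solution at first order (a tested property).  A state magnitude
above `1e6` aborts with a diagnostic naming the parameter point; the
sigmoid-bounded cortical terms and the always-stable linear thalamic
pair make genuine blow-up a parameter-entry error.

## Regime classification

After discarding a 2 s transient from a 10 s run (8 s of analysed
signal, 0.125 Hz frequency resolution):

* **Fixed point** — the `PY` peak-to-peak range over the *final 2 s* is
  below `1e-5`, or below 20% of the range over the *first 2 s* of the
  analysed window.  The relative test matters: near the oscillatory
  boundary the model has weakly damped foci whose ringing outlives any
  fixed window, and an attractor holds its amplitude while a focus loses
  most of it.  With only the absolute test, classification is not stable
  under doubling the transient window; with both tests it is (a tested
  invariant).
* **Oscillatory** — the fundamental is the dominant periodogram
  frequency; at or above 15 Hz the label is `FAST_OSC`, below 15 Hz it
  is `SWD` when the extrema rate (minima plus maxima, with a 5%-of-range
  prominence filter) reaches at least 1.5 per fundamental period.  The
  nominal spike-plus-wave count is 2; the working threshold sits below
  it because periodogram bin quantisation scatters the measured ratio
  around 2 for clean periodic waves.  The 15 Hz split was chosen so the
  20–30 Hz fast dynamics and the 2–4.5 Hz spike-wave rhythms fall on
  opposite sides with a wide margin.
* **Bistable** — a parameter point is simulated from five initial
  states: the origin, the endpoint of a 2 s run-in from the origin, and
  three corners of the explored box (`PY, IN ∈ [0,1]`,
  `TC, RE ∈ [0,2]`).  Mixed fixed-point/oscillatory outcomes give
  `BISTABLE`.  In this calibration the coexistence band along the
  frontier is thin and its fixed-point basin is smaller than any generic
  initial spread, so an all-oscillatory verdict is additionally
  cross-examined by a Newton search for an equilibrium with an analytic
  Jacobian: a *linearly stable* equilibrium coexisting with a simulated
  oscillation is rigorous evidence of bistability even when no
  trajectory of the spread settles there.  The converse (hidden limit
  cycle behind an all-fixed-point verdict) is not detected; continuation
  sweeps in the test suite bound where that could matter.

## Frontier extraction and concordance

Cells are binarised with seizure = {`SWD`, `FAST_OSC`, `BISTABLE`} —
both the spike-wave and the fast-oscillatory regions count as
epileptogenic, and a bistable cell supports a seizure attractor by
definition.  Per grid column the frontier ordinate is the first label
flip going up the column; multi-flip columns use the flip nearest the
plane's median first-flip (tie-break).  A least-squares line through
the frontier points yields the slope sign and the seizure side; a
two-covariate logistic surface fit is available as a cross-check
(`frontier_orientation(method = "logistic")`).  The default scan ranges
(`c₁ ∈ [4,14]`, `c₈ ∈ [0,8]`, `c₇ ∈ [0,4]`, `c₉ ∈ [2,12]`) are part of
the preset; the `c₉` range starts at 2 because below that the thalamic
drive is too weak to sustain any dynamics and a second, physiologically
uninteresting fixed-point boundary would dominate the column flips.

A plane is `CONCORDANT` when its frontier slope sign equals the imaging
boundary's slope sign *and* the seizure side equals the patient side;
zero slopes give `INDETERMINATE`.

## The decision boundary

The ridge-regularised logistic objective is minimised with labels
recoded to ±1 (the objective multiplies labels into the margin, which
requires ±1 coding even though groups are stored as 0/1 semantics), the
intercept unpenalised, and `ρ = 1/n` by default.  The optimiser is
stochastic gradient descent with per-epoch shuffling, 200 epochs and
step `0.1/√epoch`, with two standard refinements that keep the stated
schedule but remove its failure modes on gFA-scale features
(standard deviations near 0.03): diagonal preconditioning (the schedule
runs in unit-variance coordinates with the penalty transformed so the
minimised objective is unchanged on the original scale) and
Polyak–Ruppert averaging of the iterates over the last half of the
epochs (the reported solution).  With `ρ > 0` the problem is strictly
convex in the weights, and the tested contract is an objective gap below
`1e-3` against a full-batch BFGS oracle with matching boundary slope
signs.  A `standardize` argument additionally rescales the *model's*
features (reported on the original scale); the default fits residuals
as-is.

## Threshold-grid statistics

At each (tract length, t-score) cell: residualise the per-subject mean
gFA on intercept + age + sex over the pooled cohort (group excluded —
the fit population is a deliberate choice, since including group would
absorb part of the effect under test); Wilcoxon rank-sum between groups
(exact enumeration when the combined n ≤ 12 without ties, otherwise the
tie- and continuity-corrected normal approximation); BH-FDR jointly
across all cells of the one region's grid (21 × 21 = 441 tests), with
zero-streamline cells excluded from the family (p = 1, d = 0, masked
out); binary masks at corrected p < 0.05 and streamline count ≥ 100
multiplied element-wise.  Cohen's d uses pooled n−1 standard deviations
with the control-minus-patient sign convention (reductions in patients
are positive), and Hedges' `1 − 3/(4N − 9)` correction where recovery
is reported.

## The synthetic-data generator

The generator emulates the *statistical* structure the pipeline
consumes, starting at the summary-measure level: a 14/18 cohort with
balanced sexes and uniform ages in the published ranges; region-level
gFA as `base + age·slope + sex·offset + group_shift + Normal(0, sd)`
with `group_shift = −d·sd` for patients; and threshold grids with an
affected rectangle (default length 20–40 mm × t-score 1.5–2.0) carrying
the effect, counts `min(400 − 15(l − 20), 400 − 600(t − 1.5))` (so
counts decrease monotonically with both thresholds and the ≥ 100 region
coincides with the default rectangle), and grid-cell dependence through
a per-subject latent term of weight 0.5 shared across cells — pure
independence would overstate how well FDR behaves.  Defaults for the
gFA scale (`base_mean = 0.55`, `sd = 0.03`, small age and sex effects)
are typical of white-matter gFA summaries.

What it does *not* emulate: spatial tract geometry, voxel-level noise,
the permutation null of the connectometry software, scanner/site
effects, or any within-subject correlation between the two boundary
features (exposed as a generator argument, default independent).
Passing tests therefore certify the statistical machinery under the
assumed data model, not performance on real diffusion MRI.

One measured consequence of the latent term is worth stating plainly:
at the design effect size d = 1.3 and n = 14/18, the realised group
separation varies across replicates (shared-latent standard deviation
≈ 0.18·σ), and the final mask covers ≥ 80% of the affected region in
roughly three-quarters to ~85% of replicates rather than ≥ 90% — the
corresponding end-to-end recovery check in the test suite is strict and
currently fails at that rate; the mask never extends outside the
affected region and pure-null grids show any-rejection rates within the
FDR level.

## Problem sizes and runtimes

Default scans are 21 × 21 cells × 5 initial conditions × 10 s
integrations; the robustness checks re-scan the `c₁`–`c₈` plane at
11 × 11 under ±10% perturbations of `c₇`/`c₉`.  Effect-size calibration
uses 500 replicates per effect; grid-procedure checks use 25 replicates
per arm.  On one CPU a full plane takes tens of seconds and the whole
test suite a few minutes.

## Known limitations

* The calibration is one point of a large parameter family; the
  qualitative frontier geometry is the claim, not the numbers.
* Regime labels from 10 s windows can still mislabel dynamics whose
  settling outlives 18 s (the doubling-invariance test bounds how often).
* The SWD fundamental of the model near the frontier (≈ 1.7–3.3 Hz) is
  at the low end of the clinical 2.5–4.5 Hz band; no claim is made
  beyond qualitative spike-wave morphology.
* The statistics pipeline assumes complete cases and exchangeable
  subjects; no site, medication or longitudinal structure.
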