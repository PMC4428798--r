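---
title: "Methods: camera photogrammetry and detectability modelling in harbourcam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: camera photogrammetry and detectability modelling in harbourcam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harbourcam)
```

`harbourcam` turns pixel coordinates of surfacing dolphins, recorded by a
fixed shore camera overlooking a harbour channel, into positions, detection
summaries, a detectability model, and a cost comparison. This vignette is
the package's own account of the science: the models, their assumptions,
the tunable parameters, and what the synthetic tests do and do not
demonstrate.

## 1. Single-camera positioning with an artificial horizon

A camera of known position and lens height cannot range a target on the
water from one image unless some reference in the scene provides absolute
angles. Here the reference is the waterline of the opposite wharf: because
the camera's height above the water and the horizontal distance to the
wharf waterline are both known, the waterline's depression below the
horizontal is known too, and any pixel below it can be converted to a
depression angle and hence a range.

For an observation at pixel column $c$ and row $r$ at time $t$:

1. **Bearing.** $\theta(c)$ is piecewise-linear in $c$ through the surveyed
   landmarks (flood lights, building corners) visible in the frame, with
   linear extrapolation beyond the outermost landmarks (flagged in the
   output). At least two landmarks are required and their bearings must be
   strictly monotone in pixel column. Lens distortion is ignored: the
   cameras this emulates were zoomed fully out and the landmark
   interpolation absorbs smooth residual distortion; the GPS calibration
   quantifies what remains.
2. **Tide-corrected height.** $h_\mathrm{eff}(t) = h_\mathrm{datum} -
   \mathrm{tide}(t)$, with the gauge series interpolated linearly in time.
   The rig height and the tide series must share one tidal datum — the
   package cannot detect a datum mismatch, so the configuration documents
   both. Times up to 30 minutes (configurable) outside the gauge series use
   the end reading; beyond that the observation is refused.
3. **Vertical scale.** Still cameras store their focal length, so
   $\mathrm{angle} = \arctan(\mathrm{offset}\cdot p / f)$ with pixel pitch
   $p$. Video frames do not; their degrees-per-pixel scale is calibrated
   from landmarks of known physical height $H$ (the wharf lights): the
   angular span of such a landmark seen from the lens is
   $\arctan(h/D) + \arctan((H-h)/D)$, and dividing by its pixel span gives
   the scale. With several height-calibrated landmarks the scales are
   averaged; the scale is computed once per rig at the reference (datum)
   water level, since recomputing it per frame would move the calibration
   with the tide for no benefit at these angular scales.
4. **Range.** The total depression is the wharf-waterline depression at the
   observation's bearing plus the angle measured down from the waterline
   row to the dolphin pixel; then $R = h_\mathrm{eff}/\tan(\delta)$. A
   pixel at or above the artificial horizon has no solution and produces a
   flagged skip record — batches never abort, and no row is silently
   dropped.
5. **Position.** Range and bearing are laid out on a local planar
   east–north frame centred on the camera and converted to latitude and
   longitude on a sphere of radius 6 378 137 m. At ranges under half a
   kilometre the planar approximation errs by far less than a pixel of
   measurement noise; the tests verify positions against an independent
   haversine oracle to centimetres.

`project_forward()` is the exact algebraic inverse of this chain. That
equivalence is deliberate: the simulator projects truth through the same
geometry the estimator inverts, so round-trip tests isolate implementation
error (required < 0.1 m over 500 random in-view positions) from model
error, which is instead probed by injecting pixel noise. Under ±1 px noise
the positioning error grows from decimetres at 50 m to roughly ten metres
at 400 m — the behaviour a user should expect from a ~5 m rig, and the
reason the calibration regression tests error against range.

## 2. GPS calibration scoring

A boat carrying a GPS occupies a sweep of stations across the field of
view; each fix is matched to the camera observation nearest in time within
±5 s (ambiguous ties are reported, not resolved silently). The error metric
is the horizontal great-circle distance (via `geosphere`); GPS altitude is
ignored. The report gives per-camera minimum / mean / maximum error and an
ordinary least-squares slope of error on range with a two-sided test at
α = 0.05. On the default synthetic rig (5 m lens height, 1 px observation
noise, 2 m GPS noise, nine fixes from 60 to 380 m) the mean error comes out
around 5–8 m, the same order as a real deployment of this design.

## 3. Field of view and detection summaries

The sampled area is the fan bounded by the camera apex, the bearing rays at
the image edges, and the opposite wharf waterline, whose distance profile
is stored per rig and interpolated linearly in bearing. The polygon is
densely sampled (0.25° steps) and its area computed by the planar shoelace
formula; a 10⁵-point Monte-Carlo point-in-polygon estimate agrees within
1%. Detection analyses use one position per transit event — the
earliest-timestamped surfacing, ties broken by smallest observation id, so
the result is order-invariant — binned half-open `[lo, hi)` at 10 m and 5°
defaults. Under uniform spatial density, expected bin counts are
proportional to the annulus-by-fan intersection areas computed by
`fov_range_bin_areas()`; a χ² test at n = 5 000 confirms the geometry and
binning agree.

## 4. The detectability model

The response is hourly presence/absence of dolphin transit events over a
06:00–18:00 recording day across two survey blocks separated by a gap of
weeks. Such series are serially dependent, so ordinary logistic regression
understates uncertainty; the package fits the marginal model

$$\mathrm{logit}\,P(y_s = 1) = \beta_0 + \beta_\mathrm{glare}\,
\mathrm{glare}_s + \dots, \qquad
\mathrm{corr}(y_s, y_{s-k}) = \alpha^{k},$$

by generalised estimating equations with an AR-1 working correlation
indexed by **calendar hour within block**: a gap of $g$ recording periods
(a missing hour, or the 13-hour overnight break) weakens the working
correlation to $\alpha^g$ rather than treating the series as contiguous.
Because that structure is Markov, each block's correlation matrix has a
tridiagonal inverse, and the fit is linear-time in the number of
observations.

Estimation alternates Fisher scoring for $\beta$ with moment estimation of
the scale $\phi$ (mean squared Pearson residual) and of $\alpha$ (lag-1
Pearson residual products over pairs exactly one period apart). The fit is
deterministic; under an independence working correlation it reproduces
`glm()` to machine precision, and on a fixed fixture it matches an
independent GEE implementation to ~1e-4 in the coefficients.

**Robust variance.** The sandwich estimator needs many effectively
independent replication units. A two-block design gives only two
cluster-level scores, which sum to zero at the solution — the block-level
sandwich is rank-1 and its Wald tests are degenerate. `gee_ar1()` therefore
accumulates the sandwich over contiguous *replication segments*: a block is
split wherever the working correlation across a recording gap falls below
0.05 (overnight, $\alpha^{13} \approx 6\times10^{-6}$ for $\alpha = 0.4$),
which yields one segment per recording day and a well-conditioned
variance. The working correlation itself remains grouped by block. A
warning is raised when fewer than five segments exist. The standard errors
reported for $\phi$ and $\alpha$ are large-sample moment approximations
(the spread of the squared residuals and of the lag-1 products); they are
descriptive, and no inference in the package depends on them.

**Data preparation** (`prepare_hourly()`) applies two deterministic,
logged, idempotent rules: keep the first record of each clock hour, and
iteratively drop records whose covariate level has ≤ 20 observations
(`min_level_n`, the conventional samples-per-level floor for this kind of
model). Every dropped row is logged with its reason; kept + dropped always
equals the input count.

**Collinearity** is screened by variance inflation factors,
$\mathrm{VIF}_j = 1/(1-R_j^2)$ from auxiliary linear regressions, dropping
the worst offender above 3 one at a time; a priority list lets the analyst
keep the scientifically preferred member of a collinear pair (the default
pipeline prefers Beaufort over cloud cover, since sea state acts on
detectability directly). Perfect collinearity is reported as infinite VIF.
Covariates are treated as numeric scores, so each gets a single-df Wald
test; after level filtering has reduced glare to {0, 1} the numeric and
factor codings coincide.

**Model reduction** (`reduce_model()`) is backward elimination by robust
Wald tests at α = 0.05 — a threshold chosen so that terms near p = 0.02,
the strength of a typical glare effect in this setting, are retained.
Marginality is respected: a main effect is only droppable once no
interaction containing it remains. Every step is recorded in a trail.

**Confounding check** (`glare_confound_check()`). Glare is structurally
absent in the middle of the day, so a glare "effect" could proxy a diurnal
pattern in dolphin transits. The check refits the final model excluding a
configurable midday window (default 09:00–13:00) — hours in which glare can
be either present or absent — and reports whether glare keeps its
significance, alongside jittered presence-over-time and glare-over-time
series for plotting.

## 5. Cost comparison

Line items (gear, labour, expendables per method) are aggregated in integer
cents, so totals are exact and order-invariant. The bundled example table
(`default_cost_items()`) describes a camera system totalling 30,485 USD and
490 labour hours against field personnel at 47,580 USD and 588 hours, with
labour dominating the difference. `perusal_time()` captures the arithmetic
that drives the labour gap: footage reviewed at 1.75× playback (the fastest
speed at which detections are not missed) takes at least
`footage / 1.75` hours — 12 h of footage in 6.86 h, i.e. 7 whole hours —
plus an optional overhead fraction for rewinding and normal-speed
re-checks.

## 6. The synthetic harbour

The simulator (`sim_config()`, `simulate_scene()`, `simulate_transits()`,
`simulate_hourly_presence()`, `simulate_calibration_run()`) generates every
input the pipeline consumes, deterministically under a seed. Its defaults
are the study conditions the package is tested under:

* a 5 m rig over a channel whose opposite wharf lies 120–450 m away,
  1440×1020 px frames, 0.03°/px true vertical scale, five landmarks
  including two 18 m wharf lights;
* a semidiurnal tide (12.42 h period, 0.4 m amplitude, 0.8 m mean, 2 cm
  gauge noise);
* two survey blocks (mid-April to early June; late June to early August)
  recorded 06:00–18:00;
* hourly covariates: glare with a deterministic diurnal base — zero through
  the middle of the day, rising toward dawn and dusk — suppressed by heavy
  cloud and jittered ±1; Beaufort and cloud as bounded reflecting random
  walks; light, haze, rain and droplets on their conventional scales;
* presence truth $\beta_0 = 0.25$, $\beta_\mathrm{glare} = -0.26$,
  $\beta_\mathrm{Beaufort} = 0$, $\alpha = 0.4$;
* transits as a Poisson stream (1.5 candidates/hour) thinned by the
  presence model, crossing the field of view on straight constant-speed
  (2 m/s) paths with exponentially spaced surfacings (mean 25 s), projected
  to pixels with 1 px noise; group-size triples satisfy min ≤ best ≤ max;
* nine calibration fixes sweeping 60–380 m with 2 m GPS jitter.

Serially correlated presence is generated by thresholding a latent AR-1
Gaussian process. The latent correlation is calibrated — via the bivariate
normal orthant probability, solved numerically — so that the *binary*
lag-1 correlation equals the target $\alpha$ at the mean marginal
probability. Thresholding preserves the marginal logistic model exactly, so
GEE coefficient recovery is a fair test; the binary correlation is constant
only approximately when covariates vary, which is part of why $\alpha$
recovery is asserted within ±0.1 rather than tighter. Infeasible
marginal/correlation combinations are refused with the attainable bound
named.

**What the simulator does not emulate:** dolphin movement beyond straight
transits, surfacing synchrony within groups, observer misdetection and
misidentification, lens distortion, GPS multipath, datum errors, or
weather-driven gaps in effort. Passing tests therefore demonstrate that the
*computations* are correct under the stated study design, not that a real
deployment will achieve these error figures.

## 7. Numerical choices and problem sizes

* Angles are degrees at every API boundary and radians internally; bearings
  are true-north clockwise. Bearings passed to the inverse landmark
  interpolation are unwrapped across the 0°/360° seam relative to the
  landmark span.
* Ties in first-detection timestamps break by smallest observation id;
  histogram bins are half-open `[lo, hi)`; rounding of whole-hour perusal
  times is half-up.
* GEE iteration stops when the largest coefficient step falls below 1e-8
  (at most 50 iterations); $\alpha$ is clamped to |α| ≤ 0.95 during
  iteration; divergence beyond |β| > 50 raises a separation warning, and
  non-convergence is an error, never a silent result.
* The test suite sizes its simulations to exercise the asymptotics that
  matter while staying fast: 500-point round trips, 10⁵-point Monte-Carlo
  area checks, n = 5 000 series for correlation calibration checks, and
  200 replicate studies of n = 343 hourly records for coefficient-recovery
  and model-selection behaviour.

## 8. Selection power at the emulated effect size

One documented property deserves emphasis. At the emulated effect size
($\beta_\mathrm{glare} = -0.26$, n = 343, α = 0.4, diurnal glare), the
efficient GEE standard error for glare is ≈ 0.10, so the expected Wald
z-statistic is ≈ 2.5 and the power to retain glare at α = 0.05 is only
about 0.65–0.70; combined with the ~10% chance of falsely retaining
Beaufort or the interaction, backward elimination recovers the exact
generating model in roughly 60% of replicate studies, not more. This is a
property of the study design, not of the estimator — a glare test at
p ≈ 0.02 in a single realisation is exactly what ~65% power looks like.
Module tests that verify the selection *machinery* therefore use a
stronger simulated effect (β = −0.9), where the procedure identifies the
generating model in well over 80% of replicates, and the acceptance suite
reports the selection rate at the emulated effect size as measured.

## 9. Known limitations

* Bearing spans that straddle true north within a single rig are supported
  only via the unwrapping heuristic; a rig whose landmarks themselves wrap
  around 0° must renumber its bearings.
* The wharf waterline is assumed static apart from tide; vessels moored
  against it would bias the artificial horizon and are not modelled.
* The robust variance relies on many effectively independent daily
  segments; designs with one short contiguous block should prefer the
  naive variance (and the package warns when segments are few).
* Costs are aggregated, not modelled: no salary scales, currency
  conversion, or discounting.
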