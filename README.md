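# harbourcam

Shore-based camera photogrammetry and detectability modelling for harbour
dolphin monitoring.

## The problem

Long-term monitoring of coastal dolphins is usually done by observers in the
field with theodolites and binoculars — costly, weather-limited, and hard on
personnel. An alternative is a fixed high-definition camera overlooking the
study area: surfacing dolphins are detected in the footage, and each
detection's **pixel coordinates** are converted into a geographic position
using only the camera's surveyed height and position, known landmarks, and
the waterline of the opposite wharf as an *artificial horizon*.

`harbourcam` implements that analysis end to end for users assessing
camera-based monitoring of a harbour channel:

* **Photogrammetric positioning** — for a surfacing at pixel `(c, r)`:

  - bearing θ by piecewise-linear interpolation of surveyed landmark
    columns;
  - tide-corrected camera height `h_eff = h_datum − tide(t)`;
  - total depression below the horizontal
    `δ = atan(h_eff / D_wharf(θ)) + s · (r − r_waterline)`,
    where `D_wharf(θ)` is the distance to the opposite wharf waterline and
    `s` the vertical pixel scale (from stored focal length for still
    cameras, or calibrated from the known heights of wharf lights for video
    frames);
  - range `R = h_eff / tan(δ)`, then position on a local planar east–north
    frame at the camera.

  The exact forward model (`project_forward()`) is also provided, so the
  simulator and the inversion are mutually consistent.

* **GPS calibration scoring** — great-circle error of estimated positions
  against boat-based GPS fixes, with an error-vs-range regression.

* **Detection analysis** — field-of-view polygon and area, first detection
  per transit event, and detection counts by range and bearing bins.

* **Detectability model** — the statistical core: a marginal binomial
  (logit) model for hourly dolphin presence fitted by **generalised
  estimating equations with an AR-1 working correlation** indexed by
  calendar hour within survey blocks,

      logit P(present_s) = β₀ + β_glare · glare_s + …,
      corr(y_s, y_{s−k}) = α^k,

  with robust (sandwich) standard errors, the study's data-preparation
  rules (hourly first-observation subsampling; dropping covariate levels
  with ≤ 20 observations), a VIF collinearity screen (threshold 3), Wald
  backward elimination, and a midday-window confounding check for the glare
  effect.

* **Cost comparison** — exact line-item aggregation of camera vs
  field-personnel costs and the accelerated-playback (1.75×) perusal-time
  arithmetic.

* **Synthetic harbour simulator** — scene, tides, transit events with
  forward-projected pixel observations, GPS calibration runs, and
  serially-correlated hourly presence series with known truth, so every
  stage is testable without field data.

## Worked example

```r
library(harbourcam)
cfg <- sim_config(seed = 42)        # synthetic harbour study conditions
result <- run_pipeline(cfg, n_hours = 400)
print(result)
```

```
harbourcam pipeline run (seed 42)
  1334 observations in 301 transit events; FOV 55897 m2
Calibration against GPS fixes
  video: n = 9, error 0.7-12.3 m, mean 6.0 m
  error vs range: slope 0.0330 m/m, r = 0.80, p = 0.010 (significant at 0.05)
Backward Wald-test model reduction (alpha = 0.05)
  step 1: glare:beaufort dropped (W = 0.72, df = 1, p = 0.397)
  step 2: beaufort dropped (W = 1.36, df = 1, p = 0.243)
  step 3: glare retained - stop (W = 9.84, df = 1, p = 0.002)
  final model: presence ~ glare
  method total_usd
1 camera     30485
2  field     47580
```

Reading this: 301 simulated dolphin transit events produced 1,334 surfacing
observations, positioned from pixels over a ~56,000 m² field of view; the
nine-point GPS calibration shows a mean positioning error of 6 m that grows
with range; backward elimination keeps glare as the only detectability
covariate; and the camera method costs 30,485 USD against 47,580 USD for
field personnel. The fitted model itself:

```r
summary(result$reduction$final)
```

```
Coefficients (robust SEs):
            Estimate Std.err  Wald Pr(>|W|)
(Intercept)   0.1450  0.1922 0.569  0.45061
glare        -0.3640  0.1161 9.837  0.00171 **

Estimated Scale Parameter: 1.013 (SE 0.0205)
Estimated Correlation Parameter (alpha): 0.4438 (SE 0.048)
Number of observations: 389 in 2 block(s)
```

More intense glare lowers the odds of detecting a transit in a given hour
(negative coefficient), and adjacent hours are strongly serially correlated
(α ≈ 0.44), which is why a GEE rather than an ordinary GLM is used.

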