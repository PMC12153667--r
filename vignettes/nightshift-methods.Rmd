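---
title: "Methods: from raw accelerometry to repeatable nightly energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw accelerometry to repeatable nightly energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nightshift)
```

`nightshift` turns raw tri-axial accelerometer counts from a collared
nocturnal mammal into hourly and nightly energy-expenditure measures, and
models those measures against weather with hierarchical circadian models.
This vignette is the package's own account of the methods: the models and
their assumptions, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where more than one defensible option existed.

## 1. ODBA from raw counts

Loggers record integer counts on three orthogonal axes. Within each
non-overlapping window of `window_s` seconds (default 2 s, tiled from the
first sample), the dynamic component of channel *c* is

$$ A_c = \frac{\bar{x}_c - (\max x_c + \min x_c)/2}{\text{counts\_per\_g}}, $$

and overall dynamic body acceleration is the L1 norm
$\mathrm{ODBA} = |A_x| + |A_y| + |A_z|$, in g units. The window midpoint
$(\max+\min)/2$ removes the static (gravity) component locally; because a
device-calibrated static reference is also a defensible reading of
"midpoint", `compute_window_odba()` accepts `midpoint = "static"` with a
per-axis reference as a configurable alternative. `counts_per_g` defaults
to `2^14` (the scale programmed into the study loggers). Windows are
assumed non-overlapping; a short trailing window is dropped.

Aggregation is exact bookkeeping: the minute value is the arithmetic mean
of its member windows (this is the "minute-averaged ODBA" used for
activity classification) and the hourly value is the sum of its member
windows (hourly mechanical energy expenditure). Partial minutes and hours
at series edges are flagged `complete = FALSE` and excluded from modeling.

## 2. Activity, bouts, nights

* **Minute activity**: minute ODBA strictly above the threshold
  (default 0.28 g, the calibrated value for this system).
* **Hourly activity**: strictly more than 30 active minutes in the hour.
  Both boundaries are deliberately strict; an hour with exactly 30 active
  minutes, or minutes exactly at the threshold, is inactive.
* **Nights** run noon-to-noon (the natural 24-h unit for a nocturnal
  animal: one night is never split across analysis days). Each night gets
  a total ODBA (sum of its hourly values), a count of active minutes, and
  a bout category: `single_bout` (all activity in one non-stop run),
  `gap_resumed` (activity, then at least `gap_min = 60` consecutive
  inactive minutes, then renewed activity), or `other` (no activity, or
  runs separated only by sub-hour gaps). The gap is evaluated at minute
  resolution.
* **Deployment-day filter**: of the noon-to-noon days overlapping a
  deployment, the first (release-day disturbance) and the last (truncated
  by recapture) are dropped. A deployment spanning two or fewer analysis
  days therefore yields nothing, with a warning.

The threshold itself can be audited with `threshold_sensitivity()`: an
Otsu-style scan that, for each candidate cut, splits log2 minute ODBA into
the two induced classes and computes the between-class variance
$w_0 w_1 (\mu_0 - \mu_1)^2$. The recommended threshold maximises this
separation. The scan table (active minutes, bout counts, statistic) is
returned so users can override the recommendation; zero minutes are
floored at half the smallest positive value before the log, which affects
only the statistic's magnitude, not the ordering of well-separated
candidates. A constant series yields an explicit degenerate flag and no
recommendation.

## 3. Solar ephemeris and night weather

Sunset and sunrise come from the standard NOAA solar-position algorithm
(solar declination and equation of time from the Julian century, hour
angle at altitude −0.833°), accurate to well under ±5 min at temperate
latitudes; polar latitudes (|lat| > 66.5°) are rejected rather than
special-cased. All pipeline timestamps live on one fixed UTC-offset clock:
deployments are days-to-weeks within a season, so no DST arithmetic is
performed anywhere.

Night weather is aggregated over hourly records whose hour-start falls in
`[sunset, sunrise)` (half-open, hour-start convention): rainfall is
**summed** — total overnight precipitation is the physically meaningful
exposure — while every other covariate is averaged. Windows missing an
expected hour are flagged incomplete, never imputed (gap-filling from
external stations is data-specific curation, out of scope).

## 4. The hierarchical hourly models

For each season separately, hourly log2 ODBA is modeled as

$$ \log_2 y_{it} = f(\mathrm{hour}_t) + \mathbf{x}_{it}^\top\beta + b_i +
\varepsilon_{it}, \qquad b_i \sim N(0, \sigma_b^2), $$

with $\varepsilon$ an AR-1 process within each individual series. The
log2 response stabilises the strong variance–mean relationship of hourly
ODBA and makes effects multiplicative (one unit = a doubling).

* $f$ is a **cyclic cubic regression spline** of hour of day (`mgcv`
  cyclic B-spline basis, `knots = 10` by default), continuous in value and
  curvature across the midnight wrap. The basis is a partition of unity,
  so its first column is dropped alongside the intercept. We use an
  unpenalised regression spline of modest dimension rather than a
  GCV-penalised smooth: with ~10 basis functions the circadian shape is
  captured, every candidate model has a well-defined parameter count, and
  all-subsets AIC comparison stays coherent. This is a deliberate
  approximation to a penalised one-step GAMM; at these basis dimensions
  the fitted circadian curves are near-identical.
* **Fixed terms** are standardized (z-scored, sample SD) weather
  covariates — with quadratic terms for temperature and rainfall formed as
  squares of the z-scores — traits (age, sex, BCI = ln mass / ln length,
  mass in kg, length in cm), and BCI interactions with sex, temperature
  and rainfall. `build_design()` refuses unstandardized covariates
  (|mean| > 0.01 or |SD − 1| > 0.01); standardization is computed per
  season on the modeling subset, and the record is kept for
  back-transforming predictions (e.g. a thermal optimum in °C is
  `mean + sd × (−β₁/(2β₂))`).
* **AR-1 residuals** are fit exactly by REML/ML (`nlme::lme`, `corAR1`)
  on an integer hourly time index, so two observations g hours apart have
  correlation ρ^g. Deployment breaks are offset by a large index jump and
  thus decorrelate — gaps "reset" by decay rather than by bookkeeping.
* **Binomial activity** models use `lme4::glmer` (adaptive Laplace;
  `nAGQ = 0` in large selection scans). Mirroring the staged reference
  design, model *selection* runs without residual autocorrelation; the
  selected specification can then be refit by penalised quasi-likelihood
  with an AR-1 working correlation (`MASS::glmmPQL`). Classification
  accuracy and MCC are computed from *conditional* predictions (individual
  effects included) at a 0.5 cut — the conditional choice is documented
  here because the alternative (population-level) is also defensible;
  conditional predictions answer "how well can this fitted model classify
  this animal's hours", which is the operational question for threshold
  validation. (Quasi-)separable data break the PIRLS iterations; the fit
  falls back to a fixed-effects logistic model and flags `separation`.

Hours with zero summed ODBA cannot be log-transformed; they are excluded
from the Gaussian response but still count as inactive hours in the
binomial model — the two responses deliberately see different data.

**All-subsets selection** enumerates every subset of the full term set
that respects marginality (quadratic only with its linear term,
interaction only with both mains) and skips candidates containing both
members of any forbidden collinear pair (|Pearson r| ≥ 0.7 by default — a
conventional screening threshold in ecology, configurable). Gaussian
candidates are ranked by ML AIC (ties broken toward fewer parameters);
the table reports ΔAIC and, for each term, the percentage of candidates
within 2 AIC of the best that contain it. The enumeration is bounded
(4096 candidates) and refuses larger sets.

**Daily predictions** sum `2^η̂` over 24 scenario hours; the standard
error is by the delta method on the linear predictor (gradient
`ln 2 · 2^η̂ · x`), cross-checked in the tests against Monte-Carlo
simulation from the coefficient distribution.

## 5. Repeatability, plasticity, classification quality

* **ICC** (repeatability) is `var(ind) / (var(ind) + var(resid))` from the
  night-scale mixed model of total nightly ODBA (and, separately, nightly
  active minutes) on night-averaged covariates. The model floor is 5
  individuals with 3 nights each (configurable); below that the variance
  decomposition is not trustworthy and the fit refuses.
* **Random slopes** are compared to the random-intercept base one
  covariate at a time, with the slope uncorrelated with the intercept
  (one extra variance parameter), by ML AIC and by a likelihood-ratio
  test with the 50:50 $\chi^2_0\!:\!\chi^2_1$ boundary mixture. A test
  statistic of exactly 0 returns p = 1 by convention.
* **Plasticity surfaces** predict daily ODBA over a temperature grid at
  named BCI levels (other covariates at their standardized mean, 0); grid
  points outside the fitted covariate range are flagged as extrapolation.
* **Cross-season consistency** correlates conditional-mode individual
  intercepts between seasonal fits (Spearman, on individuals shared by
  both seasons; omitted with a note below 3 shared individuals).
* **MCC** uses the confusion-count closed form with the denominator
  computed as the square root of the product of marginal totals (exact at
  the ±1 endpoints); zero-denominator tables return 0 with an
  `undefined` attribute. Cross-validation assigns whole individual-nights
  to folds so no night is split between training and test.

## 6. The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every recovery claim is evaluated.

* **Weather** (`simulate_weather()`): hourly temperature is a sinusoidal
  diurnal cycle (amplitude 4 °C, peak mid-afternoon) around a day-level
  AR-1 anomaly (SD 2.5 °C, ρ 0.6) plus hourly noise (SD 0.5 °C); rainfall
  is zero-inflated exponential (80% dry hours, 0.5 mm mean when wet);
  wind, humidity and soil moisture are truncated Gaussians; soil
  temperatures at 10 and 30 cm are exponential smoothings of air
  temperature (coefficients 0.75 and 0.975). The smoothing construction
  deliberately induces the strong air/soil-temperature correlation
  (r ≈ 0.85 at 10 cm) that exercises the collinearity screen, without an
  explicit covariance matrix. These defaults describe a temperate spring;
  they are the fixed study conditions of the test batteries, not tuning
  dials.
* **Individuals** (`simulate_individuals()`): masses 7–14 kg, lengths
  68–82 cm, ages 2–10 y, uniform — adult badger ranges; BCI is computed by
  the same `compute_bci()` the analysis uses; intercepts are
  $N(0, \sigma_b^2)$ on the log2 scale.
* **Hourly ODBA** (`simulate_hourly_odba()`): exactly the model of §4,
  with a bimodal nocturnal circadian profile (dusk and pre-dawn peaks) and
  AR-1 residuals of marginal SD $\sigma_e$. Covariates and traits are
  standardized over the emitted deployment rows — precisely what the
  downstream analysis does — so generative β are on the modeling scale.
  Activity ground truth comes either from a logistic model
  (`activity_logit_params`) or from thresholding the implied flat minute
  mean (`hourly / 1800`).
* **Raw windows** (`synthesize_raw_windows()`): inverts the ODBA pipeline.
  Each 2-s window gets a symmetric ±h excursion pair (so the window
  midpoint is exactly zero) plus a constant fill level that sets the mean;
  integer rounding bounds the round-trip error below one count
  quantization unit (1/2¹⁴ g ≈ 6 × 10⁻⁵). Gravity is a constant
  `+counts_per_g` on the z axis; counts stay within the signed 16-bit
  logger range. The sampling rate is not fixed by the hardware description
  available, so it defaults to 50 Hz and is configurable — the 2-s window
  and the 2¹⁴ scale are rate-agnostic.
* **Night records** (`simulate_nightly_records()`): a direct night-scale
  Gaussian generator with known variance components, used for ICC
  recovery. With hourly aggregation and ρ = 0, the night-level ICC implied
  by the hourly generator converges to
  $\sigma_b^2 / (\sigma_b^2 + \sigma_e^2 / H)$ for H aggregated hours; the
  direct generator sidesteps that scaling when the target ICC itself is
  the quantity under test.

What the generator does **not** emulate: biomechanics (dynamic
acceleration is statistical, not kinematic), behaviour-specific
signatures, device drift and temperature sensitivity, missing-data
patterns of real field deployments, and social or spatial structure.
Passing recovery tests therefore demonstrate that the estimators are
consistent and unbiased *under the assumed model*, not that the model is
true of any particular field system.

## 7. Problem sizes and numerical conventions

The recovery batteries run at 20 individuals × 200 h with 25 seeded
replicates (selection consistency at 20 × 100 h, 25 replicates; smaller
unit-test variants at 6–16 individuals); these sizes give per-replicate
standard errors comfortably inside the tolerances asserted (ρ and ICC
within ±0.1, thermal optimum within ±0.5 °C, interaction sign in ≥80% of
replicates) while keeping the default test run fast. Every stochastic
routine takes an explicit seed, and identical seed + configuration
reproduces bit-identical tables.

Other conventions: AIC is always `−2 logLik + 2k` with k the full
estimated-parameter count; ML (never REML) likelihoods are compared across
fixed-effect structures; `lme` uses `optim` with raised iteration caps and
non-convergence is reported, not silently accepted; boundary estimates
(individual variance → 0) are flagged, not errors; AIC ties go to the
smaller model.

## 8. Known limitations

* The AR-1 correlation treats gaps by geometric decay (ρ^g) rather than a
  hard reset; for the hourly gaps produced by zero-ODBA exclusions the two
  are practically indistinguishable, but for pathological gap structures
  an explicit series split would differ.
* The unpenalised cyclic spline trades a little circadian flexibility for
  exact AIC bookkeeping; with K = 10 this matters only for profiles with
  features narrower than ~2.4 h.
* `glmmPQL`'s penalised quasi-likelihood yields no valid AIC; the AR-1
  binomial refit therefore reports coefficients and classification
  quality, and selection must happen (as designed) before the AR-1 stage.
* ICC is computed from intercept and residual variances only; models with
  random slopes have condition-dependent repeatability that a single ICC
  does not summarise.
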