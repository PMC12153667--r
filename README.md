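# nightshift

Accelerometry-based energetics, activity budgets and individual
repeatability for nocturnal mammals.

## The problem

Animal-borne tri-axial accelerometers let field ecologists measure how much
mechanical energy a wild animal spends, minute by minute, without observing
it. For a nocturnal, sett-dwelling mammal such as the European badger
(*Meles meles*), the questions that follow are: how does nightly energy
expenditure respond to weather, do individuals differ consistently from one
another (repeatability), and do individuals differ in *how* they respond to
the environment (plasticity)? `nightshift` implements that full analysis
chain for researchers in biologging and movement ecology:

1. **Raw counts → ODBA.** Overall dynamic body acceleration per 2-s window
   is the L1 norm of the dynamic channel components,

   `ODBA = |A_x| + |A_y| + |A_z|`,

   where each `A_c = (mean(c) − midpoint(c)) / counts_per_g` over the
   window, with `midpoint = (max + min)/2` and `counts_per_g = 2^14` by
   default. Windows are averaged to minutes (for activity classification)
   and summed to hours (hourly mechanical energy expenditure).
2. **Activity budgets.** A minute is active when its ODBA exceeds a
   calibrated threshold (default 0.28 g); an hour is active when strictly
   more than 30 of its minutes are; nights run noon-to-noon and are
   segmented into bouts (`single_bout`, `gap_resumed` after a ≥60-min rest,
   or `other`). A sensitivity scan (`threshold_sensitivity()`) exposes the
   between-class-variance statistic used to place the threshold.
3. **Hierarchical weather-response models.** Hourly log2 ODBA (Gaussian)
   and hourly activity (binomial) are modeled with a cyclic cubic
   regression spline of hour of day, standardized weather covariates
   (including quadratic temperature and rainfall and a BCI×temperature
   interaction), individual traits (age, sex, body-condition index
   `BCI = ln(mass)/ln(length)`), random individual intercepts, and AR-1
   residual autocorrelation. All-subsets AIC selection respects marginality
   and a collinearity screen.
4. **Repeatability and plasticity.** Nightly totals are modeled against
   night-averaged (sunset-to-sunrise) weather; repeatability is the
   intra-class correlation `ICC = var(ind) / (var(ind) + var(resid))`.
   Random-slope comparisons, BCI×temperature plasticity surfaces,
   cross-season intercept correlations and per-night disparity ratios
   quantify individual differences. Classifier quality is scored by
   accuracy, the Matthews correlation coefficient and grouped k-fold
   cross-validation.

A fully parameterised synthetic-data generator (weather, cohorts, hourly
ODBA, and raw logger windows that invert the ODBA pipeline) provides ground
truth for parameter-recovery testing throughout.

## Worked example

Simulate a 15-badger cohort over nine days with known generative
parameters, then fit the hourly model and check what comes back:

```r
library(nightshift)

wx   <- simulate_weather(season_config(), n_days = 9, seed = 42)
ind  <- simulate_individuals(15, sigma_individual = 0.3, seed = 43)
coh  <- synthetic_cohort(ind, wx)
pars <- true_parameters(
  beta = c(temp = 0.3, temp_sq = -0.2, bci = 0.1, bci_temp = 0.2),
  sigma_individual = 0.3, sigma_resid = 0.5, rho = 0.4)
hours <- simulate_hourly_odba(coh, pars, seed = 44)

spec <- model_spec("log2_odba", c("temp", "temp_sq", "bci", "bci_temp"),
                   knots = 8)
fit <- fit_lmm_ar1(hours, spec)
fit
#> Hierarchical fit ( log2_odba ), n = 3240
#>   AIC 4650.8 | logLik -2310.4 | k 15
#>   R2 0.660
#>   var(ind) 0.1018 | var(resid) 0.2842 | ICC 0.264 | rho 0.408
```

The generator used `rho = 0.4`, intercept SD 0.3 and residual SD 0.5, so
the implied hourly ICC is `0.09 / (0.09 + 0.25) = 0.265`; the fit returns
0.264 and `rho = 0.408`. The fixed effects recover the generative
coefficients (truth 0.3, −0.2, 0.1, 0.2):

```r
subset(fit$coefficients, term %in% c("temp", "temp_sq", "bci", "bci_temp"))
#>   term     estimate     se        p
#> 1 temp        0.310 0.0276 1.21e-28
#> 2 temp_sq    -0.189 0.0141 7.45e-40
#> 3 bci         0.166 0.0836 6.84e- 2
#> 4 bci_temp    0.201 0.0136 5.64e-48
```

Nightly repeatability from a night-scale model with equal variance
components (true ICC 0.5):

```r
nd <- simulate_nightly_records(20, 14, sigma_individual = 1,
                               sigma_resid = 1, seed = 45)
fit_nightly_model(nd, c("temp", "rain"))$decomposition$icc
#> [1] 0.579
```

A negative ICC bias or excess here would indicate a broken variance
decomposition; values fluctuate around 0.5 across seeds.

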