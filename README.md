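# dendroflux

Individual-tree time-series analysis of daily stem girth increments
against soil moisture potential and temperature, for electronic
dendrometer-band (dendroband) records from everwet tropical forest.

Stem girth measured continuously on a band mixes slow radial growth with
much larger diurnal swelling and shrinkage driven by sap flux. `dendroflux`
turns raw half-hourly girth and soil-sensor records into per-tree response
estimates:

* **Aggregation** — calendar alignment to a common frame, imputation of
  1–2-slot gaps by the mean of the bounding values, daily mean girth
  `gthm` (cm, complete 48-slot days only), and one-day increments
  `gthi = (gthm[i+1] − gthm[i]) · 10³` (cm/1000/day).
* **Soil moisture cleaning** — per-sensor "offset" (0.95-quantile
  subtraction, positives clamped) and "strict" (clamp to [−1000, 0] kPa)
  variants of soil moisture potential (SMP), the logger-temperature
  correction −(T − 20)/4 kPa, station averaging, dry-spell detection
  (runs > 3 days at or below −150 kPa offset SMP), and running rainfall
  totals.
* **Diurnal profiles** — within-day relative girth change
  `gthch = (girth_t − girth_1)/girth_1 · 10⁴` referenced to midnight,
  mean profiles over consecutive 18-day sub-periods, and a Student-t
  confidence envelope of the wet-period sub-period means against which
  dry-period profiles are compared slot by slot.
* **Rain adjustment** — a per-band OLS quadratic of `gthi` in `ln(rain)`
  on rain days plus a zero-rain mean, whose residuals replace `gthi` in
  the dry period to strip bark-swelling artefacts of showers.
* **The statistical core** — generalized least squares regression with
  exact-likelihood stationary ARMA(p, q) errors, the field's standard
  model for temporally autocorrelated increment series:

      gthi_i = β₀ + β_S · (−√|SMP_{i−1}|) + β_T · TEMP_i + ε_i,
      ε ~ ARMA(2,2)

  with ARIMA order selection (AIC over p, q ≤ 2), lag scans, Bonferroni
  correction, Granger causality F-tests, squared-residual ACF and
  GARCH(1,1) volatility diagnostics, three-part subseries recombination
  (df = n/3 − 2), prediction of missing coefficients from diurnal maxima,
  and reduced-major-axis comparison of coefficient sets.  Coefficients
  are size-standardized by 50/gbh.
* **A synthetic stand** — a fully seeded generator (18 banded trees, four
  stations with 3–4 SMP sensors each, an everwet rainfall regime with
  three embedded dry spells) with known per-tree true coefficients, used
  to validate every stage end to end.

## Worked example

Simulate one wet-period tree, run the pipeline, and estimate its SMP and
temperature responses:

```r
library(dendroflux)

cfg     <- sim_config(start = as.Date("2007-03-15"), end = as.Date("2008-09-16"))
climate <- simulate_climate(cfg, seed = 1)
tree    <- cfg$trees[1, ]                  # band g11, gbh 31 cm
band    <- simulate_tree(climate, tree, cfg, seed = 5001)

daily <- band_daily(band, cfg$wet_window)  # align, impute, gthm, gthi
drv   <- smp_station_drive(climate$sensors)
smp_t <- smp_regression_transform(drv$smp[match(daily$date, drv$date)])
X     <- cbind(smp1  = c(NA, smp_t[-nrow(daily)]),   # SMP lagged one day
               temp0 = climate$temp[match(daily$date, climate$dates)])
ok    <- complete.cases(daily$gthi, X)

fit_gls_arma(daily$gthi[ok], X[ok, ], order = c(2, 2))
#> GLS with ARMA(2,2) errors, exact ML (n = 548)
#>         term estimate      se      t         p
#>  (Intercept) -14.0000 2.27300 -6.160 1.411e-09
#>         smp1   0.4886 0.06685  7.309 9.668e-13
#>        temp0   0.6134 0.08329  7.365 6.598e-13
#> AR: 1.362 -0.6174
#> MA: -0.7506 0.2497
#> sigma^2 = 3.612, logLik = -978.975, AIC = 1973.95
```

The `smp1` coefficient (0.49 ± 0.07 cm/1000 per unit of −√kPa) recovers
this tree's planted response (`cfg$trees$beta_s[1]` = 0.558, within
1.1 SE): the tree grows faster when yesterday's soil was wetter.  The
`temp0` coefficient (0.61 ± 0.08, truth 0.682) is the same-day
temperature response, and the fitted AR/MA parameters track the
generator's ARMA(2,2) noise (AR 1.2, −0.5; MA −0.6, 0.3).
`scale_coefficient(0.4886, 31)` standardizes the slope to a 50-cm-gbh
tree for cross-tree comparison.

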