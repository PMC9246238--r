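---
title: "Girth increments, soil moisture and temperature: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Girth increments, soil moisture and temperature: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroflux)
```

## The problem

Electronic dendrometer bands record stem girth every half hour.  The
record mixes three signals of very different size: slow radial growth
(millimetres per year), diurnal swelling and shrinkage as water moves
through the stem's elastic tissues (tens of micrometres per day), and
day-to-day changes in tree water status driven by soil moisture and
evapotranspiration demand.  `dendroflux` estimates, tree by tree, how the
daily girth increment responds to soil moisture potential (SMP) the day
before and to temperature the same day, with the temporal autocorrelation
of the increment series modelled explicitly, and compares everwet
("wet") and drought-affected ("dry") periods.

## The response and the covariates

The response is the one-day increment of daily mean girth,
`gthi = (gthm[i+1] − gthm[i]) · 10³` in cm/1000 per day.  Daily means use
only days with all 48 half-hour slots present; taking the mean first and
differencing across days (rather than averaging within-day increments)
keeps the response an actual girth difference.  Differencing also removes
the accumulated growth trend, which is why no further detrending is done
and why the production fits never difference again (`d = 0` throughout;
the selection grid may consider `d = 1` but its role is diagnostic).

SMP enters as `−√|SMP|` to relieve the strong left skew of tension data;
the transform is monotone, so signs of coefficients read the same as on
the raw scale.  SMP is lagged one day and temperature unlagged — the lag
structure the data support most strongly — and both can be scanned over
lags 0–2.  Coefficients are standardized to a 50-cm-gbh tree
(`coef · 50/gbh`) for comparison across trees.

## GLS with exact-likelihood ARMA errors

The core model is `y = Xβ + ε` with `ε` stationary Gaussian ARMA(p, q),
default (2, 2).  The likelihood is exact, not conditional: for candidate
ARMA parameters the error autocorrelation function is evaluated, the
observations are whitened by a Durbin–Levinson pass (an `O(n²)` C++
kernel — no n × n matrix is formed), and β and the innovation variance
are profiled out in closed form.  The optimiser therefore works over only
the p + q correlation parameters, expressed through partial
autocorrelations via `tanh`, so every iterate is stationary and
invertible by construction.  Estimation is full ML rather than REML so
the likelihood is comparable with the AIC-based order-selection grid; a
`fixed` argument fits GLS at known ARMA parameters for oracle checks.

Numerical choices: the optimiser starts at white noise with up to five
deterministically jittered restarts (results are reproducible with no
seed); persistent failure falls back to `q − 1`, the usual remedy when
the coefficient matrix is near non-invertible, and is flagged.  Standard
errors come from the GLS covariance at the fitted ARMA parameters with
residual variance on `n − k` df, and p-values use the t distribution with
`n − k` df (the paper-scale samples, n = 550 and 98, make this nearly
identical to the normal approximation, but it is the conservative
choice).  With order (0, 0) the fit reduces to OLS exactly, which the
tests assert to 1e-8; the test suite also cross-checks the full ARMA(2,2)
fit against `nlme::gls(corARMA)`, which agrees in coefficients, SEs and
log-likelihood.

Two-term fits report marginal coefficients without centring;
when an interaction is of interest the predictors should be centred by
the caller to tame collinearity.

## Diagnostics around the core

*Order selection* grids `p, q ≤ 2`, `d ∈ {0, 1}` through `stats::arima`
with the covariate as an exogenous regressor, picking minimum AIC (ties:
smaller `p + q`, then smaller `q`).  *Granger causality* uses the
partitioned-RSS F-test with `p = 2` own- and cross-lags.
*Non-stationarity* is screened by the ACF of squared residuals (emphasis
on lags 1–3; the "strong" verdict needs all three outside ±1.96/√n with
a very small Ljung–Box p) and characterized by a hand-rolled Gaussian
QML GARCH(1,1) with `ω > 0`, `α, β ≥ 0`, `α + β < 1` enforced through
the parameterisation.  Volatile series are re-fitted in three subseries
(a custom split can isolate the volatile middle); the recombined
estimate is the mean of the outer parts, its SE the root mean square of
their SEs, t their mean, on `n/3 − 2` df — 181.3 for a 550-day series.
The "root mean square (geometric mean)" wording in the source material
is internally contradictory; the RMS formula is what is implemented.

## Diurnal profiles and the envelope test

Within-day change is `gthch = (girth_t − girth_1)/girth_1 · 10⁴`,
referenced to midnight; any missing slot voids the whole day.  The ×10⁴
scaling is taken as authoritative (it reproduces the working range of
0 to ~20) even though such values are conventionally read as "per mille".
The wet period is cut into consecutive 18-day sub-periods (550 days →
30 blocks, 10 trailing days ignored) and the envelope is the Student-t
interval of the 30 sub-period means, default 99% (config-switchable —
95% is also in circulation for display purposes), treating sub-periods
as independent.  A dry-period mean falling outside any slot rejects
equality of diurnal patterns at 1 − level.  Heavy-rain days (≥ 10 mm)
are excluded from dry-period profiles only; whether to exclude them from
wet profiles as well is switchable (default off — wet-period bark is
already wet, so the artefact mechanism is absent).

## Rain adjustment

Dry-period showers rewet dry bark, which swells under the band.  Per
band, `gthi` on days with ≥ 1 mm rain is regressed on a quadratic in
`ln(rain)` (current-day rainfall, or previous-day for bands that respond
with a one-day delay), the zero-rain mean is computed separately, and
the residuals about curve and mean replace `gthi` downstream.  Days with
trace rain (< 1 mm) join the zero pool by default: such showers are too
small to affect band readings.  OLS is appropriate here — the artefact
is a physical response to wetting, common to all days of a band, and
the residualization is idempotent.

## What the synthetic stand emulates

The generator reproduces the study's dimensions and statistical
structure with known truth: 18 banded trees of six species over four
stations, a 550-day wet window and a 98-day dry window containing three
dry spells of 18, 17 and 18 days.  Its components, and the reasoning
behind the non-obvious choices:

* **Rainfall** is zero-inflated gamma, everwet regime ~8.1 mm/day.
  Light drizzle stays frequent through the dry period (the field dry
  period had rain on 60 of 98 days) and spells keep light showers plus
  rare heavy (12–45 mm) ones; short showers do not recharge the dry
  topsoil, so spell SMP stays low regardless.
* **Soil moisture** follows a slow bucket:
  `smp[t] = clamp(smp[t−1] + 0.45·rain − ET(temp) − 9·exp(smp/25), −120, 0)`
  outside spells, giving an everwet equilibrium near −35 kPa, values
  rarely below −50 kPa, and month-scale memory (drainage is fast near
  saturation and negligible when dry).  Spell days are forced to
  −300 ± 15 kPa (capped at −180): droughts develop faster than the
  everwet dynamics, and the day after a spell is reset to −60 kPa
  (rapid rewetting), so planted spell windows are recoverable exactly.
* **Sensors** add a positive per-sensor bias (0.5–6 kPa, exercising the
  offset cleaning), Gaussian noise, and — on each station's last sensor,
  only on very dry days when poor soil contact makes it plausible —
  unrealistic spikes to −1200..−2000 kPa (exercising the strict clamp).
  Station 4 fails from January 2010, mirroring the station without
  usable dry-period records.
* **The driving covariate** for the trees is the offset-cleaned
  across-station SMP mean (`smp_station_drive()`), not the latent bucket
  state.  This is deliberate: planting the truth on the latent state
  would make parameter-recovery tests measure the mismatch between the
  latent and its cleaned reconstruction (the √ transform near zero
  turns the cleaning shift into a sizeable slope distortion), rather
  than the calibration of the GLS estimator, which is what those tests
  are for.  Physically it reads as trees responding to the soil-water
  state the station sensors characterize.
* **Tree increments** follow the core model with ARMA(2,2) noise
  (AR 1.2, −0.5; MA −0.6, 0.3; innovation SD 1.5 cm/1000), per-tree
  growth rates converted to a mean daily increment, and planted
  coefficients spanning both signs within guilds (overstorey SMP
  responses negative, understorey mostly positive, smallest scaled
  magnitude 0.6 so sign recovery is statistically attainable).
* **Diurnal shape** is a fixed zero-at-midnight curve with a
  mid-morning peak and mid-afternoon trough, scaled per tree (larger in
  the understorey).  Because the same shape repeats daily it cancels in
  `gthi`.
* **Bark swelling** on dry-period rain days arrives as
  `b₁·ln(rain) + b₂·ln(rain)²` (cm/1000) scaled by bark dryness
  (`|SMP|/300`, capped at 1) and decays at 0.95/day while the bark
  re-dries.  The persistence matters: an artefact that fully rebounds
  the next day cancels out of the regression slope and would leave
  nothing for the rain adjustment to correct.  With these settings raw
  dry-period fits attenuate the SMP coefficient by roughly a quarter —
  the magnitude reported for this artefact — and the adjustment
  recovers most of it.
* **Missingness**: random single and paired half-hour gaps (imputable
  by the bounding-mean rule) plus one five-day outage per band placed
  outside the analysis windows.

What the generator does *not* emulate: root-depth mechanisms behind
negative SMP responses (negative coefficients are simply planted),
hydraulic architecture or stomatal control, spatial heterogeneity of SMP
between stations (one latent series drives all stations), band thermal
expansion, and within-day hysteresis.  Passing tests therefore show that
the estimators are calibrated and the pipeline is faithful under the
assumed data-generating structure — not that the structure itself is the
true field mechanism.

## Problem sizes used in validation

The validation suite fits the wet scenario at its full length (n = 550
days; 200 repetitions for coverage and bias), the dry scenario at n = 98,
Granger size at 1000 repetitions (n = 300) and power at 200 (n = 500),
dry-spell recovery on 100 seeded climates, and envelope coverage on 2000
replicates of 30 sub-periods.  Heavier module checks (order-selection
consistency, GARCH recovery, end-to-end sign classification) run at
reduced repetition counts chosen so the modal or mean behaviour is still
unambiguous; the GARCH check compares against Monte-Carlo SDs
(0.0295, 0.0264, 0.0588 for ω, α, β at n = 2000) estimated once from a
60-repetition reference run.

## Known limitations

* The exact-ML fit assumes a gapless response span; gaps must be
  imputed upstream (the 1–2-unit bounding-mean rule, plus explicitly
  requested longer day-level fills) or the span restricted.
* GARCH(1,1) QML is quasi-likelihood; its LR test against constant
  variance sits on the parameter boundary and the χ² p-value is
  conservative.
* The offset cleaning anchors each sensor's upper tail at zero; level
  comparisons between sensors are therefore relative, which is the
  intended use (defining wet/dry), not an absolute calibration.
* `compute_agr` uses a 365.25-day year; the difference from a 365-day
  convention is under 0.1%.
* Basal area is computed from girth assuming circular stems.
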