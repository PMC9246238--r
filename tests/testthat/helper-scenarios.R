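# Shared simulation scenarios: one wet-period and one dry-period pipeline
# repetition (generate -> aggregate -> clean -> regress), and a GARCH(1,1)
# sampler used by the variance diagnostics tests.

# One wet-scenario repetition: simulate the default 550-day wet period for
# one tree, run the full pipeline, and fit gthi ~ -sqrt(|SMP[-1]|) + TEMP0
# with ARMA(2,2) errors.  Returns estimates, CI coverage of truth, and n.
wet_scenario_fit <- function(seed, tree_row = 1L, level = 0.95) {
  cfg <- sim_config(start = as.Date("2007-03-15"), end = as.Date("2008-09-16"))
  climate <- simulate_climate(cfg, seed)
  tree <- cfg$trees[tree_row, ]
  band <- simulate_tree(climate, tree, cfg, seed + 5000L)
  d <- band_daily(band, cfg$wet_window)
  drv <- smp_station_drive(climate$sensors)
  smp_tr <- smp_regression_transform(drv$smp[match(d$date, drv$date)])
  smp_lag1 <- c(NA, smp_tr[-nrow(d)])
  temp0 <- climate$temp[match(d$date, climate$dates)]
  ok <- !is.na(d$gthi) & !is.na(smp_lag1)
  fit <- fit_gls_arma(d$gthi[ok],
                      cbind(smp1 = smp_lag1[ok], temp0 = temp0[ok]),
                      order = c(2, 2))
  ci <- confint(fit, level = level)
  est <- coef(fit)
  list(fit = fit, n = sum(ok),
       est_s = unname(est["smp1"]), est_t = unname(est["temp0"]),
       true_s = tree$beta_s, true_t = tree$beta_t,
       cover_s = ci["smp1", 1] <= tree$beta_s && tree$beta_s <= ci["smp1", 2],
       cover_t = ci["temp0", 1] <= tree$beta_t && tree$beta_t <= ci["temp0", 2])
}

# One dry-scenario repetition: the 98-day dry period with shower (bark
# swelling) artefacts; returns the SMP-coefficient estimate from raw gthi
# and from rain-residual-adjusted gthi, plus the truth.
dry_scenario_fit <- function(seed, tree_row = 7L) {
  cfg <- sim_config(start = as.Date("2009-11-01"), end = as.Date("2010-06-30"))
  climate <- simulate_climate(cfg, seed)
  tree <- cfg$trees[tree_row, ]
  band <- simulate_tree(climate, tree, cfg, seed + 5000L)
  d <- band_daily(band, cfg$dry_window)
  drv <- smp_station_drive(climate$sensors)
  smp_tr <- smp_regression_transform(drv$smp[match(d$date, drv$date)])
  smp_lag1 <- c(NA, smp_tr[-nrow(d)])
  temp0 <- climate$temp[match(d$date, climate$dates)]
  rain <- climate$rain[match(d$date, climate$dates)]
  rf <- fit_rain_response(d$gthi, rain, "current")
  adj <- rain_residuals(d$gthi, rain, rf)
  fit_one <- function(y) {
    ok <- !is.na(y) & !is.na(smp_lag1)
    f <- fit_gls_arma(y[ok], cbind(smp1 = smp_lag1[ok], temp0 = temp0[ok]),
                      order = c(2, 2))
    unname(coef(f)["smp1"])
  }
  list(raw = fit_one(d$gthi), adj = fit_one(adj), true_s = tree$beta_s)
}

# Direct GARCH(1,1) sampler (independent of the package's fitter).
sim_garch11 <- function(n, omega, alpha, beta, seed) {
  set.seed(seed)
  z <- rnorm(n)
  e <- numeric(n)
  s2 <- omega / (1 - alpha - beta)
  for (i in seq_len(n)) {
    if (i > 1L) s2 <- omega + alpha * e[i - 1L]^2 + beta * s2
    e[i] <- sqrt(s2) * z[i]
  }
  e
}

# Build an hh_series covering `n_days` from `start` with girth given per
# slot (recycled), for quick fixtures.
make_series <- function(girth, start = as.Date("2007-03-01"),
                        n_days = length(girth) / 48, band_id = "t1") {
  w <- period_window(start, start + n_days - 1)
  hh_series(band_id, seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
                         by = 1800, length.out = n_days * 48),
            rep_len(girth, n_days * 48))
}
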