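test_that("ARIMA order selection guards short series and picks by AIC", {
  expect_error(select_arima_order(rnorm(20), rnorm(20)), "too short")
  # strong ARMA(2,2) signature: (2,2) is the modal selection
  picks <- vapply(1:12, function(s) {
    set.seed(s)
    n <- 450
    x <- rnorm(n)
    y <- 0.5 * x + as.numeric(
      arima.sim(list(ar = c(1.2, -0.5), ma = c(-0.6, 0.3)), n))
    o <- select_arima_order(y, x)
    sprintf("%d,%d", o$p, o$q)
  }, character(1))
  expect_equal(names(which.max(table(picks))), "2,2")
  # white noise: (0,0) is the modal selection
  picks0 <- vapply(1:16, function(s) {
    set.seed(s)
    x <- rnorm(500)
    y <- 0.5 * x + rnorm(500)
    o <- select_arima_order(y, x)
    sprintf("%d,%d", o$p, o$q)
  }, character(1))
  expect_equal(names(which.max(table(picks0))), "0,0")
})

test_that("Bonferroni flags use alpha / m", {
  expect_true(bonferroni_flags(0.002, m = 18))
  expect_false(bonferroni_flags(0.003, m = 18))
  expect_equal(bonferroni_flags(c(0.04, 0.06), m = 1), c(TRUE, FALSE))
})

test_that("the Granger F matches the partitioned-RSS oracle and lmtest", {
  for (s in 1:20) {
    set.seed(600 + s)
    n <- 150
    x <- as.numeric(arima.sim(list(ar = 0.5), n))
    y <- 0.3 * c(0, x[-n]) + rnorm(n)
    g <- granger_test(y, x, p = 2)
    # independent OLS oracle
    yy <- y[3:n]
    Xr <- cbind(1, y[2:(n - 1)], y[1:(n - 2)])
    Xu <- cbind(Xr, x[2:(n - 1)], x[1:(n - 2)])
    rss_r <- sum(lm.fit(Xr, yy)$residuals^2)
    rss_u <- sum(lm.fit(Xu, yy)$residuals^2)
    f_or <- ((rss_r - rss_u) / 2) / (rss_u / (length(yy) - 5))
    expect_equal(g$F, f_or, tolerance = 1e-10)
    ref <- lmtest::grangertest(x, y, order = 2)
    expect_equal(g$F, ref$F[2], tolerance = 1e-8)
    expect_equal(g$p_value, ref$`Pr(>F)`[2], tolerance = 1e-8)
  }
  expect_error(granger_test(rnorm(100), rep(1, 100)), "singular")
})

test_that("squared-residual ACF separates i.i.d. noise from GARCH volatility", {
  # i.i.d.: about 5% of lags stray outside the bounds, never 'strong'
  frac <- vapply(1:30, function(s) {
    set.seed(700 + s)
    a <- acf_squared_residuals(rnorm(1500))
    mean(a$outside)
  }, numeric(1))
  expect_lt(mean(frac), 0.12)
  strong_iid <- vapply(1:30, function(s) {
    set.seed(700 + s)
    acf_squared_residuals(rnorm(1500))$verdict == "strong"
  }, logical(1))
  expect_lte(mean(strong_iid), 0.05)
  # persistent GARCH: verdict 'strong' almost always
  strong <- vapply(1:15, function(s)
    acf_squared_residuals(sim_garch11(2000, 0.1, 0.15, 0.75, s))$verdict ==
      "strong", logical(1))
  expect_gte(mean(strong), 0.9)
  expect_error(acf_squared_residuals(rep(1, 100)), "constant")
})

test_that("GARCH(1,1) QML recovers parameters within Monte-Carlo error", {
  # MC SDs at truth (0.1, 0.15, 0.7), n = 2000: (0.0295, 0.0264, 0.0588)
  ests <- t(vapply(1:6, function(s) {
    f <- fit_garch11(sim_garch11(2000, 0.1, 0.15, 0.7, 800 + s))
    c(f$omega, f$alpha, f$beta)
  }, numeric(3)))
  mc_sd <- c(0.0295, 0.0264, 0.0588)
  expect_true(all(abs(colMeans(ests) - c(0.1, 0.15, 0.7)) <
                    3 * mc_sd / sqrt(6)))
  # homoscedastic input: persistence small or LR insignificant
  calm <- vapply(1:8, function(s) {
    set.seed(900 + s)
    f <- fit_garch11(rnorm(800))
    f$alpha + f$beta < 0.2 || f$lr_p > 0.05
  }, logical(1))
  expect_gte(mean(calm), 0.75)
  expect_warning(fit_garch11(rnorm(50)), "fewer than 100")
})

test_that("subseries recombination follows the stated formulas", {
  # identical parts reproduce the per-part values
  set.seed(41)
  x1 <- rnorm(100)
  y1 <- 1 + 0.5 * x1 + rnorm(100)
  ss <- split_and_recombine(rep(y1, 3), rep(x1, 3), order = c(0, 0))
  one <- ss$fits[[1]]$coefficients
  expect_equal(ss$combined$estimate, one$estimate, tolerance = 1e-9)
  expect_equal(ss$combined$se, one$se, tolerance = 1e-9)
  expect_equal(ss$combined$t, one$t, tolerance = 1e-9)
  expect_equal(ss$df, 300 / 3 - 2)
  # stationary series: combined within 2 combined-SEs of the full fit
  hits <- vapply(1:6, function(s) {
    set.seed(950 + s)
    n <- 330
    x <- rnorm(n)
    y <- 0.7 * x + as.numeric(arima.sim(list(ar = 0.4, ma = 0.2), n))
    full <- fit_gls_arma(y, cbind(x = x), order = c(1, 1))
    ss2 <- split_and_recombine(y, cbind(x = x), order = c(1, 1))
    row <- ss2$combined[ss2$combined$term == "x", ]
    abs(row$estimate - coef(full)["x"]) < 2 * row$se
  }, logical(1))
  expect_gte(sum(hits), 5L)
})

test_that("missing coefficients are predicted from gthch_max and back-scaled", {
  # exactly collinear inputs: zero residual variance
  gmax <- c(2, 4, 6, 8, 10)
  known <- 3 - 0.5 * gmax
  pr <- predict_missing_coefficients(known, gmax, c(5, 7), c(100, 50))
  expect_equal(pr$pred_scaled, c(0.5, -0.5), tolerance = 1e-8)
  expect_equal(pr$pred, c(0.5 * 2, -0.5), tolerance = 1e-8)
  expect_lt(max(pr$se_scaled), 1e-6)
  expect_error(predict_missing_coefficients(1:2, 1:2, 3, 50), "at least 3")
  # leave-one-out: held-out value inside the 95% prediction interval
  set.seed(42)
  gmax2 <- runif(13, 2, 14)
  coefs <- 2 - 0.4 * gmax2 + rnorm(13, 0, 0.3)
  inside <- vapply(seq_along(gmax2), function(i) {
    pr_i <- predict_missing_coefficients(coefs[-i], gmax2[-i], gmax2[i], 50)
    abs(coefs[i] - pr_i$pred_scaled) < qt(0.975, 10) * pr_i$se_scaled
  }, logical(1))
  expect_gte(mean(inside), 0.8)
})

test_that("relative-humidity checks are null-calibrated and detect effects", {
  set.seed(43)
  n <- 300
  tdry <- rnorm(n, 30.2, 0.6)
  rh <- 100 - 2.5 * (tdry - 25) + rnorm(n, 0, 2)
  # no RH effect beyond temperature
  gthi0 <- 0.5 + 0.9 * (tdry - 30) + as.numeric(
    arima.sim(list(ar = c(0.4, 0.1), ma = c(0.2, 0.1)), n))
  null_res <- rh_conditional_tests(gthi0, tdry, rh)
  expect_gt(null_res$resid_fit$coefficients$p[2], 0.01)
  # planted RH effect: residual-fit and nested interaction agree in sign
  gthi1 <- gthi0 + 0.35 * (rh - mean(rh))
  alt <- rh_conditional_tests(gthi1, tdry, rh)
  expect_lt(alt$resid_fit$coefficients$p[2], 0.01)
  expect_gt(alt$resid_fit$coefficients$estimate[2], 0)
  expect_gt(alt$interaction$estimate, 0)
  # an empty temperature slice is skipped with a note
  res2 <- rh_conditional_tests(gthi0, tdry, rh,
                               slices = list(c(45, 46), c(30.0, 30.6)))
  expect_true(res2$slices$skipped[1])
  expect_false(res2$slices$skipped[2])
})

test_that("reduced major axis slopes follow the SD-ratio definition", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(rma_slope(x, x)$slope, 1)
  expect_equal(rma_slope(x, x)$intercept, 0)
  expect_equal(rma_slope(x, 2 * x + 1)$slope, 2)
  set.seed(44)
  a <- rnorm(40); b <- -1.3 * a + rnorm(40, 0, 0.5)
  r <- rma_slope(a, b)
  expect_equal(r$slope, sign(cor(a, b)) * sd(b) / sd(a))
  expect_equal(r$intercept, mean(b) - r$slope * mean(a))
})
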