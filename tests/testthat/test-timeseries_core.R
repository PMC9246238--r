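test_that("align_to_frame produces the full window grid and alters nothing", {
  s <- make_series(rep(31, 48 * 3), start = as.Date("2010-01-05"))
  w <- period_window("2010-01-01", "2010-01-10")
  a <- align_to_frame(s, w)
  expect_length(a$girth, 10 * 48)
  expect_equal(sum(!is.na(a$girth)), 3 * 48)
  expect_equal(a$girth[!is.na(a$girth)], rep(31, 3 * 48))
  # one-day window
  expect_length(align_to_frame(s, period_window("2010-01-05", "2010-01-05"))$girth, 48)
  # window outside the data: all missing, not an error
  far <- align_to_frame(s, period_window("2011-01-01", "2011-01-02"))
  expect_true(all(is.na(far$girth)))
})

test_that("window day counts match brute-force calendar iteration", {
  set.seed(11)
  for (i in 1:200) {
    start <- as.Date("2004-01-01") + sample.int(2500, 1)
    end <- start + sample.int(900, 1) - 1
    oracle <- length(seq(start, end, by = "day"))
    w <- period_window(start, end)
    expect_identical(window_length_days(w), as.integer(oracle))
  }
  # a leap day is counted
  expect_identical(window_length_days(period_window("2008-02-28", "2008-03-01")), 3L)
})

test_that("short-gap imputation fills 1-2 runs with the bounding mean only", {
  expect_equal(as.numeric(impute_short_gaps(c(1, NA, 2))), c(1, 1.5, 2))
  expect_equal(as.numeric(impute_short_gaps(c(1, NA, NA, 3))), c(1, 2, 2, 3))
  expect_equal(as.numeric(impute_short_gaps(c(1, NA, NA, NA, 3))),
               c(1, NA, NA, NA, 3))
  # edge runs stay missing
  expect_equal(as.numeric(impute_short_gaps(c(NA, 2, 3))), c(NA, 2, 3))
  # idempotent, never changes observed values
  set.seed(2)
  x <- rnorm(300)
  x[sample(300, 60)] <- NA
  once <- impute_short_gaps(x)
  expect_equal(as.numeric(impute_short_gaps(as.numeric(once))),
               as.numeric(once))
  obs <- !is.na(x)
  expect_equal(as.numeric(once)[obs], x[obs])
})

test_that("daily mean girth requires complete 48-slot days", {
  s <- make_series(rep(31, 48 * 2))
  d <- daily_mean_girth(s)
  expect_equal(d$gthm, c(31, 31))
  expect_true(all(d$complete))
  # 47 of 48 present -> missing under the completeness rule
  g <- rep(31, 48 * 2); g[5] <- NA
  s2 <- make_series(g)
  d2 <- daily_mean_girth(s2)
  expect_true(is.na(d2$gthm[1]) && !d2$complete[1])
  expect_equal(daily_mean_girth(s2, require_complete = FALSE)$gthm[1], 31)
  # linear ramp vs direct summation oracle
  ramp <- seq(30, 30.5, length.out = 48)
  d3 <- daily_mean_girth(make_series(ramp, n_days = 1))
  expect_equal(d3$gthm, sum(ramp) / 48)
})

test_that("daily increments use the x1000 scale and telescope", {
  d <- data.frame(band_id = "t", date = as.Date("2010-01-01") + 0:2,
                  gthm = c(31.000, 31.002, 31.002))
  di <- daily_increment(d)
  expect_equal(di$gthi, c(2, 0, NA))
  set.seed(3)
  d2 <- data.frame(band_id = "t", date = as.Date("2010-01-01") + 0:199,
                   gthm = 30 + cumsum(rnorm(200, 0, 1e-3)))
  di2 <- daily_increment(d2)
  expect_equal(sum(di2$gthi[1:199]) * 1e-3, d2$gthm[200] - d2$gthm[1])
  # increments across a gthm gap are missing
  d2$gthm[50] <- NA
  di3 <- daily_increment(d2)
  expect_true(all(is.na(di3$gthi[49:50])))
})

test_that("agr matches the unit-conversion identity with mean gthi", {
  n <- 400
  d <- data.frame(band_id = "t", date = as.Date("2010-01-01") + 0:(n - 1),
                  gthm = 30 + 0.001 * (0:(n - 1)))
  w <- period_window(d$date[1], d$date[n])
  expect_equal(compute_agr(d, w), 0.001 * (n - 1) * 10 * 365.25 / (n - 1))
  d$gthm <- rep(30, n)
  expect_equal(compute_agr(d, w), 0)
  # simulated linear growth: agr ~= 3.6525 * mean(gthi) within 2%
  d3 <- daily_increment(data.frame(band_id = "t",
                                   date = as.Date("2010-01-01") + 0:(n - 1),
                                   gthm = 30 + 0.0007 * (0:(n - 1))))
  ratio <- compute_agr(d3, w) / mean(d3$gthi, na.rm = TRUE)
  expect_lt(abs(ratio / 3.6525 - 1), 0.02)
})

test_that("coefficient size-standardization is exact and invertible", {
  expect_equal(scale_coefficient(1, 50), 1)
  expect_equal(scale_coefficient(1, 100), 0.5)
  set.seed(4)
  coefs <- rnorm(20); gbh <- runif(20, 10, 120)
  expect_equal(backscale_coefficient(scale_coefficient(coefs, gbh), gbh), coefs)
})

test_that("neighbourhood BA/d matches a brute-force pairwise oracle", {
  focal <- list(band_id = "f", x = 0, y = 0)
  none <- data.frame(band_id = "a", gbh = 50, x = 10, y = 10)
  expect_equal(neighbourhood_ba_d(focal, none), 0)
  # one neighbour with BA 100 cm^2 at 2 m -> 50 cm^2/m
  gbh100 <- sqrt(100 * 4 * pi)
  one <- data.frame(band_id = "a", gbh = gbh100, x = 2, y = 0)
  expect_equal(neighbourhood_ba_d(focal, one), 50)
  expect_error(neighbourhood_ba_d(focal,
    data.frame(band_id = "a", gbh = 50, x = 0, y = 0)), "zero distance")
  set.seed(5)
  stand <- data.frame(band_id = paste0("n", 1:80),
                      gbh = runif(80, 5, 120),
                      x = runif(80, -8, 8), y = runif(80, -8, 8))
  oracle <- 0
  for (i in 1:80) {
    d <- sqrt(stand$x[i]^2 + stand$y[i]^2)
    if (d <= 5 && d > 0 && stand$gbh[i] >= 10)
      oracle <- oracle + stand$gbh[i]^2 / (4 * pi) / d
  }
  expect_equal(neighbourhood_ba_d(focal, stand), oracle)
})

test_that("tree table validation enforces the size-class threshold", {
  tr <- data.frame(band_id = c("a", "b"), gbh = c(40, 80))
  out <- tree_table(tr)
  expect_identical(out$scl, c(1L, 2L))
  tr$scl <- c(2L, 2L)
  expect_error(tree_table(tr), "scl inconsistent")
  expect_error(tree_table(data.frame(band_id = "a", gbh = -1)), "positive")
})
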