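test_that("logger-temperature correction is the stated linear rule", {
  expect_equal(correct_smp_for_logger_temp(0, 20), 0)
  expect_equal(correct_smp_for_logger_temp(0, 16), 1)
  expect_equal(correct_smp_for_logger_temp(-100, 30), -102.5)
})

test_that("offset cleaning subtracts the per-sensor 0.95-quantile and clamps", {
  expect_equal(offset_transform(rep(0, 30)), rep(0, 30))
  x <- as.numeric(1:100)
  q <- sort(x)[95] + 0.05 * (sort(x)[96] - sort(x)[95])  # type-7 order stats
  expect_equal(offset_transform(x), pmin(x - q, 0))
  set.seed(6)
  y <- rnorm(200, 5, 20)
  expect_lte(max(offset_transform(y)), 0)
  # near-idempotent: the cleaned series' own 0.95-quantile sits at zero
  # up to the interpolation of the order-statistic estimator
  expect_lt(max(abs(offset_transform(offset_transform(y)) -
                      offset_transform(y))), 0.1)
  expect_error(offset_transform(rnorm(10)), "need >= 20")
})

test_that("strict cleaning clamps to [-1000, 0] and is idempotent", {
  expect_equal(strict_transform(c(5, -2000, -50)), c(0, -1000, -50))
  set.seed(7)
  z <- rnorm(100, -500, 800)
  expect_equal(strict_transform(strict_transform(z)), strict_transform(z))
})

test_that("station averaging takes per-day means over sensors with data", {
  d <- data.frame(sensor_id = rep(c("a", "b"), each = 2),
                  station = 1, date = rep(as.Date("2010-01-01") + 0:1, 2),
                  smp = c(-100, -100, -200, NA))
  out <- station_average_smp(d)
  expect_equal(out$smp, c(-150, -100))
  # all-sensor-missing day stays missing
  d$smp <- c(NA, -100, NA, -300)
  expect_true(is.na(station_average_smp(d)$smp[1]))
  # random panel vs loop oracle
  set.seed(8)
  pan <- expand.grid(sensor_id = letters[1:4],
                     date = as.Date("2010-01-01") + 0:19)
  pan$station <- 1L
  pan$smp <- rnorm(80, -50, 10)
  pan$smp[sample(80, 10)] <- NA
  out2 <- station_average_smp(pan)
  for (i in seq_len(nrow(out2))) {
    v <- pan$smp[pan$date == out2$date[i]]
    expect_equal(out2$smp[i], mean(v, na.rm = TRUE))
  }
})

test_that("dry-spell detection keeps maximal runs longer than 3 days", {
  dates <- as.Date("2010-01-01") + 0:29
  smp <- rep(-50, 30); smp[6:15] <- -200
  sp <- detect_dry_spells(dates, smp)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$duration_days, 10L)
  expect_equal(sp$start, dates[6]); expect_equal(sp$end, dates[15])
  expect_equal(sp$mean_smp, -200)
  # 3-day excursion below threshold is not a spell
  smp2 <- rep(-50, 30); smp2[10:12] <- -300
  expect_equal(nrow(detect_dry_spells(dates, smp2)), 0L)
  # a missing day breaks a run
  smp3 <- rep(-200, 30); smp3[15] <- NA; smp3[1:7] <- -50
  sp3 <- detect_dry_spells(dates, smp3)
  expect_equal(sp3$duration_days, c(7L, 15L))
  # invariant to prepending/appending above-threshold days, vs scan oracle
  set.seed(9)
  for (r in 1:25) {
    smp4 <- ifelse(runif(60) < 0.45, -200, -50)
    d4 <- as.Date("2010-01-01") + 0:59
    sp4 <- detect_dry_spells(d4, smp4)
    padded <- detect_dry_spells(as.Date("2009-12-27") + 0:69,
                                c(rep(-10, 5), smp4, rep(-10, 5)))
    expect_equal(sp4[c("start", "end")], padded[c("start", "end")])
    r4 <- rle(smp4 <= -150)
    oracle_n <- sum(r4$values & r4$lengths >= 4)
    expect_equal(nrow(sp4), oracle_n)
  }
})

test_that("window lengths reproduce the printed study spans", {
  expect_equal(window_length_days(period_window("2010-02-18", "2010-03-07")), 18L)
  expect_equal(window_length_days(period_window("2010-03-18", "2010-06-23")), 98L)
  expect_equal(window_length_days(period_window("2010-05-01", "2010-05-01")), 1L)
})

test_that("running rainfall totals are trailing sums with an NA head", {
  expect_equal(running_rain_total(rep(5, 15), 10),
               c(rep(NA, 9), rep(50, 6)))
  imp <- rep(0, 30); imp[15] <- 100
  rt <- running_rain_total(imp, 10)
  expect_equal(rt[15:24], rep(100, 10))   # persists for n days
  expect_equal(rt[c(14, 25)], c(0, 0))
  set.seed(10)
  r <- rgamma(60, 1, 0.2)
  cs <- cumsum(r)
  expect_equal(running_rain_total(r, 20)[20:60], cs[20:60] - c(0, cs[1:40]))
})

test_that("the regression transform is -sqrt(|SMP|)", {
  expect_equal(smp_regression_transform(0), 0)
  expect_equal(smp_regression_transform(-100), -10)
  expect_equal(smp_regression_transform(-36.3), -sqrt(36.3))
})

test_that("SMP-rainfall correlations are computed on the sqrt scales", {
  set.seed(12)
  rft <- rgamma(500, 4, 0.05)
  smp_coupled <- -(0.5 * sqrt(rft) - 10)^2
  cc <- smp_rain_correlation(smp_coupled, rft)
  expect_gt(abs(cc$r), 0.99)
  expect_equal(cc$n, 500)
  smp_noise <- -rgamma(500, 5, 0.1)
  ci <- smp_rain_correlation(smp_noise, rft)
  expect_lt(abs(ci$r), 2.6 / sqrt(500))
  anti <- smp_rain_correlation(-(5 + 0.3 * sqrt(rft))^2, rft)
  expect_lt(anti$r, -0.99)
  # t statistic matches cor.test
  ct <- cor.test(-sqrt(abs(smp_noise)), sqrt(rft))
  expect_equal(ci$t, unname(ct$statistic))
})

test_that("the cleaned across-station drive averages only stations with data", {
  sens <- expand.grid(sensor_id = c("s11", "s12", "s21"),
                      date = as.Date("2010-01-01") + 0:39)
  sens$station <- ifelse(sens$sensor_id == "s21", 2L, 1L)
  set.seed(13)
  sens$smp <- rnorm(nrow(sens), -40, 8) + 3
  sens$smp[sens$sensor_id == "s21" & sens$date > as.Date("2010-01-30")] <- NA
  drv <- smp_station_drive(sens)
  expect_equal(nrow(drv), 40L)
  expect_true(all(!is.na(drv$smp)))  # station 1 still reports
  # manual recomputation
  cl <- sens
  for (id in unique(cl$sensor_id))
    cl$smp[cl$sensor_id == id] <- offset_transform(cl$smp[cl$sensor_id == id])
  st <- station_average_smp(cl)
  man <- tapply(st$smp, st$date, mean, na.rm = TRUE)
  expect_equal(drv$smp, as.numeric(man[format(drv$date)]))
})
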