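#' Logger-temperature correction of SMP
#'
#' Equitensiometer readings drift with the logger's internal temperature;
#' the correction is `-(T - 20) / 4` kPa at logger temperature `T` degrees C
#' (about 2.5 kPa, or 2%, at 30 degrees C).
#'
#' @param smp_raw raw soil moisture potential, kPa.
#' @param temp logger temperature, degrees C.
#' @return Corrected SMP, `smp_raw - (temp - 20) / 4`, kPa.
#' @export
correct_smp_for_logger_temp <- function(smp_raw, temp) {
  stopifnot(all(is.finite(smp_raw)), all(is.finite(temp)))
  smp_raw + (-(temp - 20) / 4)
}

#' 'Offset' SMP cleaning
#'
#' Converted sensor series often carry many small positive values.  Per
#' sensor, the upper 0.95-quantile is subtracted and remaining positive
#' values are set to zero, so the cleaned series is everywhere <= 0.
#' Quantiles use linear interpolation of order statistics (type 7).
#'
#' @param smp numeric SMP series for one sensor, kPa (NAs allowed).
#' @param probs upper quantile to subtract (default 0.95).
#' @param min_obs minimum observed values required for a stable quantile.
#' @return Cleaned series, same length, all values <= 0.
#' @export
offset_transform <- function(smp, probs = 0.95, min_obs = 20L) {
  n_obs <- sum(!is.na(smp))
  if (n_obs < min_obs)
    stop(sprintf("only %d observed values; need >= %d for the %.2f-quantile",
                 n_obs, min_obs, probs))
  out <- smp - quantile(smp, probs, na.rm = TRUE, names = FALSE, type = 7)
  pmin(out, 0)
}

#' 'Strict' SMP cleaning
#'
#' Element-wise clamp to `[-1000, 0]` kPa: positives (sensor artefacts) to
#' zero, unrealistically low readings up to -1000 kPa.
#'
#' @param smp numeric SMP series, kPa.
#' @return Clamped series.
#' @export
strict_transform <- function(smp) pmin(pmax(smp, -1000), 0)

#' Average cleaned SMP over sensors
#'
#' Unweighted per-day mean over the sensors of a station (or a topographic
#' class, via `group`); a day is missing only when every contributing
#' sensor is missing.
#'
#' @param sensors long data frame with columns `sensor_id`, `date`, `smp`,
#'   and a grouping column (default `station`).
#' @param group name of the grouping column.
#' @return Data frame `group`, `date`, `smp` (daily group means).
#' @export
station_average_smp <- function(sensors, group = "station") {
  stopifnot(all(c("sensor_id", "date", "smp", group) %in% names(sensors)))
  out <- aggregate(sensors["smp"],
                   by = list(group = sensors[[group]], date = sensors$date),
                   FUN = function(v) if (all(is.na(v))) NA_real_
                                     else mean(v, na.rm = TRUE))
  names(out)[1] <- group
  out[order(out[[group]], out$date), , drop = FALSE]
}

#' Cleaned across-station daily SMP series
#'
#' The standard recipe for the regression covariate: per-sensor
#' [offset_transform()] over the sensor's whole record (sensors with
#' fewer than `min_obs` observations stay missing), unweighted averaging
#' within stations, then an unweighted mean across stations with data.
#'
#' @param sensors long data frame (`sensor_id`, `station`, `date`, `smp`).
#' @param min_obs minimum observations per sensor for cleaning.
#' @return Data frame `date`, `smp` (daily cleaned across-station mean).
#' @export
smp_station_drive <- function(sensors, min_obs = 20L) {
  cl <- sensors
  cl$smp <- ave(cl$smp, cl$sensor_id, FUN = function(v) {
    if (sum(!is.na(v)) < min_obs) return(rep(NA_real_, length(v)))
    offset_transform(v, min_obs = min_obs)
  })
  st <- station_average_smp(cl)
  out <- aggregate(st["smp"], by = list(date = st$date),
                   FUN = function(v) if (all(is.na(v))) NA_real_
                                     else mean(v, na.rm = TRUE))
  out[order(out$date), c("date", "smp")]
}

#' Detect dry spells in a daily SMP series
#'
#' Maximal runs of consecutive days with SMP at or below `threshold`,
#' retained when longer than 3 days (`min_run_days = 4`).  The default
#' threshold -150 kPa applies to 'offset'-cleaned values; use -100 kPa for
#' 'strict' values.  A missing day terminates a run.
#'
#' @param dates contiguous daily `Date` vector.
#' @param smp daily (station- or class-averaged) SMP, kPa.
#' @param threshold run-membership threshold, kPa.
#' @param min_run_days minimum run length in days.
#' @return Data frame `start`, `end`, `duration_days`, `mean_smp`; zero rows
#'   when no spell qualifies.
#' @export
detect_dry_spells <- function(dates, smp, threshold = -150, min_run_days = 4L) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(smp))
  if (length(dates) > 1L && any(diff(dates) != 1))
    stop("`dates` must be a contiguous daily sequence")
  dry <- !is.na(smp) & smp <= threshold
  r <- rle(dry)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run_days
  data.frame(
    start = dates[starts[keep]],
    end = dates[ends[keep]],
    duration_days = r$lengths[keep],
    mean_smp = vapply(which(keep), function(i)
      mean(smp[starts[i]:ends[i]]), numeric(1)),
    row.names = NULL)
}

#' Trailing running rainfall totals
#'
#' Sum of the current day and the previous `n - 1` days; the first `n - 1`
#' entries (and any window containing a missing day) are `NA`.
#'
#' @param rain daily rainfall, mm.
#' @param n window length in days (10, 20, 30, 40 or 50 in routine use).
#' @return Numeric vector of running totals, same length as `rain`.
#' @export
running_rain_total <- function(rain, n) {
  stopifnot(n >= 1L, n <= length(rain))
  as.numeric(stats::filter(rain, rep(1, n), sides = 1))
}

#' Square-root transform of SMP for regression
#'
#' `-sqrt(|SMP|)`: reduces the strong left skew of SMP while preserving
#' order (monotone non-increasing in `|SMP|`).
#'
#' @param smp SMP in kPa (<= 0 after cleaning).
#' @return Transformed values.
#' @export
smp_regression_transform <- function(smp) -sqrt(abs(smp))

#' Correlation of SMP with running rainfall totals
#'
#' Pearson correlation between `-sqrt(|SMP|)` and `sqrt(rft)` over jointly
#' observed days (both sides sqrt-transformed to achieve linearity), with
#' the t statistic and sample size.
#'
#' @param smp daily SMP, kPa.
#' @param rft running rainfall total, mm (same length).
#' @return List with `r`, `t`, `n`, `p` (two-sided).
#' @export
smp_rain_correlation <- function(smp, rft) {
  stopifnot(length(smp) == length(rft))
  x <- smp_regression_transform(smp)
  y <- sqrt(rft)
  ok <- complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 jointly observed days")
  r <- cor(x[ok], y[ok])
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, n = n, p = 2 * pt(-abs(t), n - 2))
}
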