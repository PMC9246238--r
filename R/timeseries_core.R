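#' @useDynLib dendroflux, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats acf aggregate arima arima.sim ARMAacf Box.test coef
#'   complete.cases cor cor.test lm lm.fit optim pchisq pf plogis pt qlogis
#'   qt quantile resid rgamma rnorm runif sd setNames var predict
#' @importFrom utils read.delim write.table
NULL

SLOTS_PER_DAY <- 48L

#' Half-hourly girth series
#'
#' Container for one dendroband's half-hourly girth record.  Timestamps must
#' lie on a 30-minute grid and be strictly increasing; a calendar day runs
#' 00:00-23:30 (48 slots), with the midnight slot opening the new day.
#' Timestamps are stored as POSIXct in UTC: the grid is local clock time and
#' carries no daylight-saving shifts.
#'
#' @param band_id single band identifier, e.g. `"g11"`.
#' @param time POSIXct (or coercible) timestamps on the half-hour grid.
#' @param girth stem girth in cm per timestamp; `NA` marks missing readings.
#' @param imputed optional logical flag per value (default all `FALSE`).
#' @return An object of class `hh_series`.
#' @export
hh_series <- function(band_id, time, girth, imputed = NULL) {
  time <- as.POSIXct(time, tz = "UTC")
  girth <- as.numeric(girth)
  if (length(time) != length(girth))
    stop("`time` and `girth` must have equal length")
  secs <- as.numeric(time)
  if (any(secs %% 1800 != 0))
    stop("timestamps must lie on a 30-minute grid")
  if (length(time) > 1L && any(diff(secs) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(girth <= 0, na.rm = TRUE))
    stop("girth must be positive where present")
  if (is.null(imputed)) imputed <- rep(FALSE, length(girth))
  structure(
    list(band_id = as.character(band_id)[1L], time = time,
         girth = girth, imputed = as.logical(imputed)),
    class = "hh_series")
}

#' @export
print.hh_series <- function(x, ...) {
  n <- length(x$girth)
  cat(sprintf("<hh_series %s: %d half-hour slots, %d missing, %d imputed>\n",
              x$band_id, n, sum(is.na(x$girth)), sum(x$imputed)))
  invisible(x)
}

#' Analysis period window
#'
#' An inclusive calendar window; the day count is `end - start + 1`.
#'
#' @param start,end `Date` (or coercible) endpoints, `end >= start`.
#' @param label one of `"wet"`, `"dry"`, `"custom"`.
#' @return An object of class `period_window`.
#' @export
period_window <- function(start, end, label = c("custom", "wet", "dry")) {
  label <- match.arg(label)
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("window endpoints must be valid dates")
  if (end < start) stop("`end` must not precede `start`")
  structure(list(start = start, end = end, label = label),
            class = "period_window")
}

#' @export
print.period_window <- function(x, ...) {
  cat(sprintf("<period_window [%s] %s .. %s (%d days)>\n", x$label,
              format(x$start), format(x$end), window_length_days(x)))
  invisible(x)
}

#' Inclusive day count of a window
#'
#' @param window a [period_window()].
#' @return Integer number of calendar days, endpoints included.
#' @export
window_length_days <- function(window) {
  stopifnot(inherits(window, "period_window"))
  as.integer(window$end - window$start) + 1L
}

window_grid <- function(window) {
  n_days <- window_length_days(window)
  origin <- as.POSIXct(paste(format(window$start), "00:00:00"), tz = "UTC")
  origin + 1800 * seq_len(n_days * SLOTS_PER_DAY) - 1800
}

#' Align a half-hourly series to a common time frame
#'
#' Expands (or crops) a series onto the full half-hour grid of `window`:
#' exactly `48 * (end - start + 1)` slots.  Slots absent from the input are
#' marked missing; observed values are never altered.
#'
#' @param series an [hh_series()].
#' @param window a [period_window()].
#' @return An [hh_series()] covering the full window grid.
#' @export
align_to_frame <- function(series, window) {
  stopifnot(inherits(series, "hh_series"))
  grid <- window_grid(window)
  idx <- match(as.numeric(grid), as.numeric(series$time))
  hh_series(series$band_id, grid, series$girth[idx],
            imputed = ifelse(is.na(idx), FALSE, series$imputed[idx]))
}

# Fill runs of <= max_gap consecutive NAs that are bounded by observed
# values on both sides with the mean of the bounding pair.
fill_short_gaps <- function(x, max_gap) {
  filled <- rep(FALSE, length(x))
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] || r$lengths[i] > max_gap) next
    lo <- starts[i] - 1L; hi <- ends[i] + 1L
    if (lo < 1L || hi > length(x)) next          # edge runs stay missing
    if (is.na(x[lo]) || is.na(x[hi])) next
    x[starts[i]:ends[i]] <- (x[lo] + x[hi]) / 2
    filled[starts[i]:ends[i]] <- TRUE
  }
  list(x = x, filled = filled)
}

#' Impute short gaps by the mean of the bounding values
#'
#' Runs of one or two missing values flanked by observed values on both
#' sides are replaced by the mean of the flanking pair.  Longer runs, and
#' runs touching the series edge, are left missing.  The operation is
#' idempotent and never changes observed values.
#'
#' @param x an [hh_series()], a daily series data frame (column `gthm`),
#'   or a plain numeric vector.
#' @param max_gap maximum run length to fill (default 2: an incidental or
#'   consecutive pair of missing values).
#' @return Same type as `x`, with an imputation flag
#'   (`imputed` element/column, or attribute `"imputed"` for vectors).
#' @export
impute_short_gaps <- function(x, max_gap = 2L) UseMethod("impute_short_gaps")

#' @export
impute_short_gaps.hh_series <- function(x, max_gap = 2L) {
  f <- fill_short_gaps(x$girth, max_gap)
  x$girth <- f$x
  x$imputed <- x$imputed | f$filled
  x
}

#' @export
impute_short_gaps.data.frame <- function(x, max_gap = 2L) {
  if (!"gthm" %in% names(x)) stop("daily series must have a `gthm` column")
  f <- fill_short_gaps(x$gthm, max_gap)
  x$gthm <- f$x
  x$imputed <- if ("imputed" %in% names(x)) x$imputed | f$filled else f$filled
  x
}

#' @export
impute_short_gaps.default <- function(x, max_gap = 2L) {
  f <- fill_short_gaps(as.numeric(x), max_gap)
  structure(f$x, imputed = f$filled)
}

#' Daily mean girth
#'
#' Mean girth per calendar day.  A day counts as complete only when all 48
#' half-hour slots are present (after any imputation); with
#' `require_complete = TRUE` (the default, as used throughout) incomplete
#' days get a missing mean.
#'
#' @param series an [hh_series()] aligned to a window grid.
#' @param require_complete if `TRUE`, `gthm` is `NA` unless all 48 slots
#'   are present.
#' @return A data frame (`band_id`, `date`, `gthm`, `complete`, `imputed`),
#'   one row per covered day; `imputed` flags days containing any imputed
#'   half-hour value.
#' @export
daily_mean_girth <- function(series, require_complete = TRUE) {
  stopifnot(inherits(series, "hh_series"))
  n <- length(series$girth)
  if (n %% SLOTS_PER_DAY != 0)
    stop("series does not cover whole days; align it to a window first")
  day <- rep(seq_len(n / SLOTS_PER_DAY), each = SLOTS_PER_DAY)
  g <- matrix(series$girth, nrow = SLOTS_PER_DAY)
  complete <- colSums(!is.na(g)) == SLOTS_PER_DAY
  gthm <- colMeans(g)                       # NA unless complete
  if (!require_complete)
    gthm[!complete] <- colMeans(g, na.rm = TRUE)[!complete]
  data.frame(
    band_id = series$band_id,
    date = as.Date(series$time[seq(1L, n, by = SLOTS_PER_DAY)], tz = "UTC"),
    gthm = gthm,
    complete = complete,
    imputed = colSums(matrix(series$imputed, nrow = SLOTS_PER_DAY)) > 0L,
    row.names = NULL)
}

#' One-day girth increments
#'
#' Adds `gthi` = (`gthm[i+1]` - `gthm[i]`) * 10^3 in cm/1000 per day, the
#' increment from day *i* to the next.  Increments across a gap in `gthm`
#' are missing, and the last day has none.  Over any gapless span the
#' increments telescope: `sum(gthi) / 1000 == last(gthm) - first(gthm)`.
#'
#' @param daily a daily series from [daily_mean_girth()].
#' @return The input with a `gthi` column appended.
#' @export
daily_increment <- function(daily) {
  stopifnot(is.data.frame(daily), "gthm" %in% names(daily))
  n <- nrow(daily)
  gthi <- c((daily$gthm[-1L] - daily$gthm[-n]) * 1e3, NA_real_)
  daily$gthi <- gthi
  daily
}

#' Align + impute + aggregate one band in one call
#'
#' Convenience chain: [align_to_frame()], half-hourly [impute_short_gaps()],
#' [daily_mean_girth()], day-level [impute_short_gaps()] (when
#' `impute_days > 0`), then [daily_increment()].
#'
#' @param series an [hh_series()].
#' @param window a [period_window()].
#' @param max_gap half-hourly gap-fill limit (slots).
#' @param impute_days day-level gap-fill limit for `gthm` (days); the field
#'   records occasionally need longer day-level fills, configured here
#'   explicitly rather than silently.
#' @return A daily series data frame with `gthi`.
#' @export
band_daily <- function(series, window, max_gap = 2L, impute_days = 2L) {
  s <- impute_short_gaps(align_to_frame(series, window), max_gap = max_gap)
  d <- daily_mean_girth(s)
  if (impute_days > 0L) d <- impute_short_gaps(d, max_gap = impute_days)
  daily_increment(d)
}

#' Absolute growth rate over a window
#'
#' Simple-difference absolute growth rate in mm/year, from the daily mean
#' girths at (or nearest to) the window endpoints:
#' `agr = (gthm_end - gthm_start) * 10 * 365.25 / days`, where `days` is the
#' span between the two days actually used.  For near-linear growth
#' `agr` is about `3.65 * mean(gthi)` (unit conversion identity).
#'
#' @param daily a daily series with `gthm`.
#' @param window a [period_window()].
#' @return `agr` in mm/year (scalar).
#' @export
compute_agr <- function(daily, window) {
  stopifnot(is.data.frame(daily), all(c("date", "gthm") %in% names(daily)))
  ok <- !is.na(daily$gthm) & daily$date >= window$start & daily$date <= window$end
  if (sum(ok) < 2L) stop("need girth on at least two days inside the window")
  d <- daily[ok, ]
  i0 <- which.min(abs(as.numeric(d$date - window$start)))
  i1 <- which.min(abs(as.numeric(d$date - window$end)))
  span <- as.numeric(d$date[i1] - d$date[i0])
  if (span <= 0) stop("window endpoints resolve to the same day")
  (d$gthm[i1] - d$gthm[i0]) * 10 * 365.25 / span
}

#' Standardize a response coefficient to 50 cm gbh
#'
#' Multiplies a per-tree response coefficient by `50 / gbh` so trees of
#' different stem girth are comparable; [backscale_coefficient()] inverts it.
#'
#' @param coef coefficient value(s).
#' @param gbh girth at breast height, cm (> 0).
#' @return Scaled coefficient(s).
#' @export
scale_coefficient <- function(coef, gbh) {
  if (any(gbh <= 0)) stop("gbh must be positive")
  coef * 50 / gbh
}

#' @rdname scale_coefficient
#' @export
backscale_coefficient <- function(coef, gbh) {
  if (any(gbh <= 0)) stop("gbh must be positive")
  coef * gbh / 50
}

#' Distance-weighted neighbourhood basal area (BA/d)
#'
#' Local competition index for a focal tree: the sum over all neighbours
#' with `gbh >= min_gbh` within `radius` metres of basal area divided by
#' Euclidean distance, in cm^2/m.  Basal area is taken from girth assuming
#' a circular stem, `BA = gbh^2 / (4 * pi)`.  The focal tree is excluded; a
#' neighbour at zero distance is rejected (undefined weight).
#'
#' @param focal one-row data frame (or list) with `band_id`, `x`, `y`.
#' @param neighbours data frame with `band_id`, `gbh`, `x`, `y`.
#' @param radius search radius, m.
#' @param min_gbh minimum neighbour girth, cm.
#' @return BA/d in cm^2/m (scalar; 0 when no neighbour qualifies).
#' @export
neighbourhood_ba_d <- function(focal, neighbours, radius = 5, min_gbh = 10) {
  d <- sqrt((neighbours$x - focal$x)^2 + (neighbours$y - focal$y)^2)
  keep <- neighbours$band_id != focal$band_id &
    d <= radius & neighbours$gbh >= min_gbh
  if (!any(keep)) return(0)
  if (any(d[keep] == 0))
    stop("neighbour at zero distance: BA/d weight undefined")
  sum(neighbours$gbh[keep]^2 / (4 * pi) / d[keep])
}

#' Validate a tree metadata table
#'
#' Checks the per-tree covariate table (one row per band): positive `gbh`,
#' size class consistent with the overstorey threshold (`scl = 2` iff
#' `gbh > threshold`), and `CanStat` within the 1-5 scoring range.
#' Missing `scl` is derived from `gbh`.
#'
#' @param trees data frame with at least `band_id` and `gbh`; optionally
#'   `species_code`, `scl`, `station`, `x`, `y`, `CanStat`.
#' @param overstorey_gbh size-class threshold in cm (default 60).
#' @return The validated table (with `scl` filled in if absent).
#' @export
tree_table <- function(trees, overstorey_gbh = 60) {
  stopifnot(is.data.frame(trees), all(c("band_id", "gbh") %in% names(trees)))
  if (anyDuplicated(trees$band_id)) stop("duplicated band_id")
  if (any(trees$gbh <= 0)) stop("gbh must be positive")
  scl_expect <- ifelse(trees$gbh > overstorey_gbh, 2L, 1L)
  if (!"scl" %in% names(trees)) trees$scl <- scl_expect
  else if (any(trees$scl != scl_expect))
    stop("scl inconsistent with the overstorey gbh threshold")
  if ("CanStat" %in% names(trees) &&
      any(trees$CanStat < 1 | trees$CanStat > 5, na.rm = TRUE))
    stop("CanStat must lie in [1, 5]")
  trees
}
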