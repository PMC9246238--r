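#' Within-day relative girth change (gthch)
#'
#' Relative change per half-hour slot referenced to the first slot of the
#' day (midnight): `gthch[t] = (girth[t] - girth[1]) / girth[1] * 1e4`,
#' t = 1..48.  A day with any missing slot yields all-missing changes, so
#' it does not count towards period means.  Positive values indicate stem
#' swelling, negative shrinkage; the scaling brings typical values into
#' the range 0 to about 20.
#'
#' @param girth_day numeric vector of 48 half-hourly girths, cm.
#' @return Numeric vector of 48 changes (slot 1 is exactly 0), or all `NA`
#'   when the day is incomplete.
#' @export
gthch_day <- function(girth_day) {
  if (length(girth_day) != SLOTS_PER_DAY)
    stop("a day has exactly 48 half-hour slots")
  if (anyNA(girth_day)) return(rep(NA_real_, SLOTS_PER_DAY))
  (girth_day - girth_day[1L]) / girth_day[1L] * 1e4
}

#' Drop heavy-rain days before diurnal averaging
#'
#' Showers can rewet dry bark and swell it under the band, so days with
#' rainfall at or above `cutoff` (default 10 mm) are removed before
#' computing dry-period diurnal profiles.
#'
#' @param days `Date` vector of candidate days.
#' @param rain daily rainfall for those days, mm.
#' @param cutoff exclusion threshold, mm.
#' @return The retained subset of `days`.
#' @export
exclude_heavy_rain_days <- function(days, rain, cutoff = 10) {
  stopifnot(length(days) == length(rain))
  days[is.na(rain) | rain < cutoff]
}

#' Mean diurnal profiles over consecutive sub-periods
#'
#' Splits the window into `floor(days / block_days)` consecutive,
#' non-overlapping blocks (remainder days at the end are ignored) and, per
#' block, averages the [gthch_day()] profiles of its qualifying days.  A
#' 550-day window with 18-day blocks gives 30 blocks with 10 days ignored.
#'
#' @param series an [hh_series()] (need not be pre-aligned).
#' @param window a [period_window()].
#' @param block_days block length in days (default 18).
#' @param keep_days optional `Date` vector: only these days enter the
#'   block means (used to drop heavy-rain days, see
#'   [exclude_heavy_rain_days()]).
#' @param max_gap half-hourly imputation limit applied before profiling.
#' @return List of profiles, each a list with `band_id`, `block`, `start`,
#'   `end`, `values` (48 means), `n_days`; class `diurnal_profile`.
#' @export
subperiod_profiles <- function(series, window, block_days = 18L,
                               keep_days = NULL, max_gap = 2L) {
  n_days <- window_length_days(window)
  if (n_days < block_days)
    stop("window shorter than one block")
  aligned <- impute_short_gaps(align_to_frame(series, window), max_gap)
  g <- matrix(aligned$girth, nrow = SLOTS_PER_DAY)
  dates <- seq(window$start, by = 1, length.out = n_days)
  ch <- apply(g, 2L, gthch_day)               # 48 x n_days
  if (!is.null(keep_days))
    ch[, !(dates %in% as.Date(keep_days))] <- NA_real_
  n_blocks <- n_days %/% block_days
  lapply(seq_len(n_blocks), function(b) {
    cols <- ((b - 1L) * block_days + 1L):(b * block_days)
    ok <- cols[colSums(is.na(ch[, cols, drop = FALSE])) == 0L]
    structure(list(
      band_id = aligned$band_id, block = b,
      start = dates[cols[1L]], end = dates[cols[block_days]],
      values = if (length(ok)) rowMeans(ch[, ok, drop = FALSE])
               else rep(NA_real_, SLOTS_PER_DAY),
      n_days = length(ok)), class = "diurnal_profile")
  })
}

#' Confidence envelope of wet-period diurnal profiles
#'
#' Per half-hour slot, the mean of the sub-period mean profiles and
#' Student-t confidence limits `mean +/- t[level, n-1] * SD / sqrt(n)`,
#' treating sub-periods as independent.  A dry-period profile falling
#' outside these limits at any slot rejects, at `1 - level`, the null
#' hypothesis that wet and dry diurnal patterns are the same.
#'
#' @param profiles list of sub-period profiles from [subperiod_profiles()];
#'   at least 3 with data are required.
#' @param level confidence level (default 0.99).
#' @return Object of class `diurnal_envelope`: `mean`, `lower`, `upper`
#'   (48 values each), `n_subperiods`, `level`.
#' @export
wet_envelope <- function(profiles, level = 0.99) {
  vals <- vapply(profiles, function(p) p$values, numeric(SLOTS_PER_DAY))
  vals <- vals[, colSums(is.na(vals)) == 0L, drop = FALSE]
  n <- ncol(vals)
  if (n < 3L) stop("need at least 3 sub-period profiles with data")
  m <- rowMeans(vals)
  se <- apply(vals, 1L, sd) / sqrt(n)
  half <- qt(1 - (1 - level) / 2, df = n - 1L) * se
  structure(list(mean = m, lower = m - half, upper = m + half,
                 n_subperiods = n, level = level),
            class = "diurnal_envelope")
}

#' Compare a dry-period profile to the wet envelope
#'
#' @param dry a `diurnal_profile` (or a numeric vector of 48 values).
#' @param envelope a [wet_envelope()].
#' @return List with `flags` (factor of 48 values in
#'   below/inside/above) and `any_outside` (logical summary).
#' @export
compare_dry_to_envelope <- function(dry, envelope) {
  stopifnot(inherits(envelope, "diurnal_envelope"))
  v <- if (inherits(dry, "diurnal_profile")) dry$values else as.numeric(dry)
  if (length(v) != SLOTS_PER_DAY) stop("profile must have 48 slots")
  f <- ifelse(v < envelope$lower, "below",
              ifelse(v > envelope$upper, "above", "inside"))
  f <- factor(f, levels = c("below", "inside", "above"))
  list(flags = f, any_outside = any(f != "inside", na.rm = TRUE))
}

#' Diurnal extremes of a mean profile
#'
#' @param profile a `diurnal_profile` or numeric vector of 48 values.
#' @return Named numeric `c(gthch_min, gthch_max)`.
#' @export
profile_min_max <- function(profile) {
  v <- if (inherits(profile, "diurnal_profile")) profile$values
       else as.numeric(profile)
  c(gthch_min = min(v), gthch_max = max(v))
}
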