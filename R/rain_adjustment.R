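#' Fit the rain-shower (bark swelling) response of girth increments
#'
#' In the dry period, showers on otherwise dry bark can swell it under the
#' band, so part of the measured increment is an artefact of wetting
#' rather than stem-water status.  Per band, an ordinary least-squares
#' quadratic in `ln(rain)` is fitted to `gthi` on days with rain of at
#' least `min_rain` mm (current-day or previous-day rainfall), and the
#' mean `gthi` on zero-rain days is computed separately.
#'
#' Days with trace rain (0 < rain < `min_rain`) join the zero-rain pool by
#' default (`trace_to_zero = TRUE`): such light showers do not appreciably
#' affect band readings.
#'
#' @param gthi daily increments, cm/1000.
#' @param rain daily rainfall, mm (same dates as `gthi`).
#' @param which_day `"current"` regresses `gthi[i]` on `rain[i]`;
#'   `"previous"` on `rain[i-1]`.
#' @param min_rain minimum rainfall for the regression pool, mm.
#' @param trace_to_zero if `FALSE`, trace-rain days are dropped instead of
#'   pooled with zero-rain days.
#' @param min_rain_days,min_zero_days refusal thresholds.
#' @return Object of class `rain_fit`: quadratic coefficients
#'   (`intercept`, `linear`, `quadratic` on `ln(rain)`), `mean_gthi_at_zero`,
#'   counts, overall regression `F` and `p`, plus the fit frame.
#' @export
fit_rain_response <- function(gthi, rain, which_day = c("current", "previous"),
                              min_rain = 1, trace_to_zero = TRUE,
                              min_rain_days = 6L, min_zero_days = 3L) {
  which_day <- match.arg(which_day)
  stopifnot(length(gthi) == length(rain))
  r <- if (which_day == "previous") c(NA_real_, rain[-length(rain)]) else rain
  ok <- !is.na(gthi) & !is.na(r)
  rainy <- ok & r >= min_rain
  zero <- if (trace_to_zero) ok & r < min_rain else ok & r == 0
  if (sum(rainy) < min_rain_days || sum(zero) < min_zero_days)
    stop(sprintf("insufficient days: %d with rain >= %g mm (need %d), %d zero-rain (need %d)",
                 sum(rainy), min_rain, min_rain_days, sum(zero), min_zero_days))
  lr <- log(r[rainy])
  yr <- gthi[rainy]
  fit <- lm(yr ~ lr + I(lr^2))
  rss <- sum(resid(fit)^2)
  rss0 <- sum((yr - mean(yr))^2)
  df2 <- length(yr) - 3L
  Fstat <- ((rss0 - rss) / 2) / (rss / df2)
  structure(list(
    which_day = which_day,
    coefficients = setNames(coef(fit), c("intercept", "linear", "quadratic")),
    mean_gthi_at_zero = mean(gthi[zero]),
    n_rain_days = sum(rainy), n_zero_days = sum(zero),
    min_rain = min_rain, trace_to_zero = trace_to_zero,
    F = Fstat,
    p = pf(Fstat, 2, df2, lower.tail = FALSE),
    fit = fit), class = "rain_fit")
}

#' @export
print.rain_fit <- function(x, ...) {
  cat(sprintf("<rain_fit (%s-day rain): gthi ~ ln(rain) + ln(rain)^2 on %d rain days>\n",
              x$which_day, x$n_rain_days))
  print(round(x$coefficients, 4))
  cat(sprintf("zero-rain mean gthi %.4f over %d days;  F = %.2f, p = %.3g\n",
              x$mean_gthi_at_zero, x$n_zero_days, x$F, x$p))
  invisible(x)
}

#' Rain-residual girth increments
#'
#' Replaces `gthi` by its residuals about the fitted shower response: on
#' rain days the fitted quadratic curve in `ln(rain)` is subtracted, on
#' zero-rain days the zero-rain mean.  The residual series stands in for
#' `gthi` in all downstream dry-period analyses.
#'
#' @param gthi daily increments, cm/1000.
#' @param rain daily rainfall, mm.
#' @param fit a [fit_rain_response()] result.
#' @return Numeric residual series with attribute `rain_adjusted = TRUE`.
#' @export
rain_residuals <- function(gthi, rain, fit) {
  stopifnot(inherits(fit, "rain_fit"), length(gthi) == length(rain))
  r <- if (fit$which_day == "previous") c(NA_real_, rain[-length(rain)]) else rain
  b <- fit$coefficients
  out <- rep(NA_real_, length(gthi))
  rainy <- !is.na(gthi) & !is.na(r) & r >= fit$min_rain
  zero <- if (fit$trace_to_zero) !is.na(gthi) & !is.na(r) & r < fit$min_rain
          else !is.na(gthi) & !is.na(r) & r == 0
  lr <- log(r[rainy])
  out[rainy] <- gthi[rainy] - (b[1L] + b[2L] * lr + b[3L] * lr^2)
  out[zero] <- gthi[zero] - fit$mean_gthi_at_zero
  structure(out, rain_adjusted = TRUE)
}
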