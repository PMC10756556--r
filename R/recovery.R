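#' Day of functional recovery of a daily-mean series
#'
#' The recovery day is the first measurement day whose daily mean lies within
#' `tolerance_frac` of the healthy control reference and *stays* inside that
#' band on every later day of the series (the persistence clause prevents a
#' single lucky day from counting). Shrinking the tolerance can only delay
#' the estimate.
#'
#' @param days Measurement days, sorted ascending.
#' @param values Daily means, same length as `days`.
#' @param control_ref Healthy control reference value (> 0).
#' @param tolerance_frac Half-width of the recovery band as a fraction of
#'   `control_ref` (default 0.05).
#' @return The recovery day, or `NA` if the series never settles in the band.
#' @export
recovery_time <- function(days, values, control_ref, tolerance_frac = 0.05) {
  if (!length(days))
    stop_gaitrec("empty series", "gaitrec_insufficient")
  if (length(days) != length(values))
    stop_gaitrec("days and values must have equal length", "gaitrec_validation")
  if (control_ref <= 0)
    stop_gaitrec("control_ref must be > 0", "gaitrec_validation")
  if (is.unsorted(days))
    stop_gaitrec("days must be sorted ascending", "gaitrec_validation")
  inside <- abs(values - control_ref) <= tolerance_frac * control_ref
  stay <- rev(cumprod(rev(inside))) > 0  # inside from here to the end
  if (!any(stay)) return(NA_real_)
  days[which(stay)[1]]
}

#' Linear recovery rate in % body weight per month
#'
#' OLS slope of the daily means against the day, converted to calendar months
#' of 30.44 days. For a %BW parameter gaining 19 %BW over 160 days this is
#' 3.61 %BW per month.
#'
#' @param days Measurement days.
#' @param values Daily means (%BW), same length.
#' @param window Optional day range `c(from, to)` restricting the fit
#'   (inclusive); default uses the whole series.
#' @return List with `rate_per_month`, `slope_per_day` and the underlying
#'   [ols_fit()].
#' @export
recovery_rate <- function(days, values, window = NULL) {
  if (!is.null(window)) {
    keep <- days >= window[1] & days <= window[2]
    days <- days[keep]; values <- values[keep]
  }
  if (length(days) < 3L)
    stop_gaitrec("need at least 3 points in the window", "gaitrec_insufficient")
  ft <- ols_fit(days, values)
  list(rate_per_month = ft$slope * 30.44, slope_per_day = ft$slope, fit = ft)
}

#' Fit a linear recovery model to one limb and parameter
#'
#' The central longitudinal model of the monitoring pipeline: per-animal daily
#' means of one gait parameter for one limb are pooled into a per-day cohort
#' mean series, a linear trend is fitted over the consolidation window, and
#' the functional recovery day is estimated against the healthy control
#' reference.
#'
#' @param daily A `daily_summary` frame from [aggregate_daily()].
#' @param limb Limb label (default `"IH"`, the operated limb).
#' @param parameter Parameter name (default `"grf_peak_pct"`).
#' @param control_ref Healthy control reference; defaults to the package
#'   control value for the chosen limb/parameter where available.
#' @param tolerance_frac Recovery band half-width (default 0.05).
#' @param window Day range for the rate fit; default from the first session to
#'   the control-recovery day of the default trajectories (160).
#' @param animals Optional animal ids to keep (e.g. the operated group when
#'   the daily frame also contains control animals); default all.
#' @return An object of class `gait_recovery` with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods: contains the pooled series, the
#'   [ols_fit()], `rate_per_month` and `recovery_day`.
#' @export
fit_recovery <- function(daily, limb = "IH", parameter = "grf_peak_pct",
                         control_ref = NULL, tolerance_frac = 0.05,
                         window = NULL, animals = NULL) {
  s <- daily[daily$limb == limb & daily$parameter == parameter, ]
  if (!is.null(animals)) s <- s[s$animal_id %in% animals, ]
  if (!nrow(s))
    stop_gaitrec(sprintf("no daily summaries for %s / %s", limb, parameter),
                 "gaitrec_insufficient")
  pooled <- stats::aggregate(mean ~ day_postop, data = s, FUN = mean)
  pooled <- pooled[order(pooled$day_postop), ]
  if (is.null(control_ref)) {
    ctrl <- control_reference()
    side <- if (limb %in% c("IH", "CH")) "hind" else "fore"
    control_ref <- switch(parameter,
                          grf_peak_pct = ctrl[[side]]$grf_peak_pct,
                          grf_mean_pct = ,
                          imp_rel_pct = ctrl[[side]]$grf_mean_pct,
                          t_c = ctrl[[side]]$t_c,
                          imp_abs_pct_s = ctrl[[side]]$grf_mean_pct *
                            ctrl[[side]]$t_c)
  }
  if (is.null(window)) window <- c(min(pooled$day_postop), 160)
  rate <- recovery_rate(pooled$day_postop, pooled$mean, window = window)
  rec_day <- recovery_time(pooled$day_postop, pooled$mean, control_ref,
                           tolerance_frac)
  structure(list(limb = limb, parameter = parameter, series = pooled,
                 control_ref = control_ref, tolerance_frac = tolerance_frac,
                 window = window, fit = rate$fit,
                 rate_per_month = rate$rate_per_month,
                 recovery_day = rec_day,
                 n_animals = length(unique(s$animal_id))),
            class = "gait_recovery")
}

#' @export
print.gait_recovery <- function(x, ...) {
  cat(sprintf("<gait_recovery> %s %s: %+.2f %s/month (R^2 %.2f), recovery day %s (band +/-%g%% of %.3g)\n",
              x$limb, x$parameter, x$rate_per_month,
              if (x$parameter == "t_c") "s" else "%BW",
              x$fit$r_squared,
              if (is.na(x$recovery_day)) "not reached" else format(x$recovery_day),
              100 * x$tolerance_frac, x$control_ref))
  invisible(x)
}

#' @export
summary.gait_recovery <- function(object, ...) {
  cat(sprintf("Linear recovery model: %s, %s (%d animals, %d session days)\n",
              object$limb, object$parameter, object$n_animals,
              nrow(object$series)))
  cat(sprintf("  window        : days %g-%g\n", object$window[1], object$window[2]))
  cat(sprintf("  slope         : %.4f per day (%.3f per 30.44-day month)\n",
              object$fit$slope, object$rate_per_month))
  cat(sprintf("  R-squared     : %.3f (%s), p = %.3g\n",
              object$fit$r_squared, object$fit$strength, object$fit$p_value))
  cat(sprintf("  control ref   : %.3g (+/- %g%% band)\n",
              object$control_ref, 100 * object$tolerance_frac))
  cat(sprintf("  recovery day  : %s\n",
              if (is.na(object$recovery_day)) "not reached" else
                format(object$recovery_day)))
  invisible(object)
}

#' @export
coef.gait_recovery <- function(object, ...) {
  c(intercept = object$fit$intercept, slope = object$fit$slope,
    rate_per_month = object$rate_per_month)
}

#' @export
predict.gait_recovery <- function(object, days = object$series$day_postop, ...) {
  object$fit$intercept + object$fit$slope * days
}

#' @export
plot.gait_recovery <- function(x, ...) {
  graphics::plot(x$series$day_postop, x$series$mean,
                 xlab = "day post-surgery",
                 ylab = sprintf("%s (%s)", x$parameter,
                                if (x$parameter == "t_c") "s" else "%BW"),
                 main = sprintf("Recovery of %s, limb %s", x$parameter, x$limb),
                 pch = 19, ...)
  graphics::abline(h = x$control_ref, lty = 2)
  graphics::abline(h = x$control_ref * (1 + c(-1, 1) * x$tolerance_frac),
                   lty = 3, col = "grey50")
  w <- x$window
  graphics::segments(w[1], x$fit$intercept + x$fit$slope * w[1],
                     w[2], x$fit$intercept + x$fit$slope * w[2], col = 2)
  if (!is.na(x$recovery_day)) graphics::abline(v = x$recovery_day, col = 4, lty = 2)
  invisible(x)
}
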