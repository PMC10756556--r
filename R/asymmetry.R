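#' Inter-limb asymmetry index
#'
#' The classical symmetry index between the daily mean values of a gait
#' parameter on the ipsilateral (operated-side) and contralateral limbs:
#' \deqn{\mathrm{Asymmetry}(\%) = 100 \cdot
#'   \frac{|X_I - X_C|}{0.5\,(X_I + X_C)}.}
#' It is 0 for perfect symmetry and reaches its analytic maximum of 200 when
#' exactly one limb bears no load. It is symmetric in its arguments and
#' invariant to a common positive rescaling.
#'
#' @param x_ipsi Daily mean for the ipsilateral limb (>= 0).
#' @param x_contra Daily mean for the contralateral limb (>= 0); not both zero.
#' @return The asymmetry in percent, in `[0, 200]` (vectorized).
#' @examples
#' asymmetry_index(40, 40)  # 0
#' asymmetry_index(0, 40)   # 200
#' asymmetry_index(20, 42)  # 70.97
#' @export
asymmetry_index <- function(x_ipsi, x_contra) {
  if (any(x_ipsi < 0) || any(x_contra < 0))
    stop_gaitrec("asymmetry inputs must be non-negative", "gaitrec_validation")
  if (any(x_ipsi + x_contra == 0))
    stop_gaitrec("asymmetry undefined: both limbs report zero", "gaitrec_undefined")
  100 * abs(x_ipsi - x_contra) / (0.5 * (x_ipsi + x_contra))
}

#' Asymmetry series for the hind and fore limb pairs
#'
#' Computes the asymmetry index per animal and day for the hind pair (IH vs
#' CH) and the fore pair (IF vs CF) from a daily summary. Days on which either
#' limb of a pair is missing are skipped with a note; zero-denominator days
#' are emitted as flagged `NA` rows rather than dropped.
#'
#' @param summaries A `daily_summary` frame from [aggregate_daily()].
#' @param parameter Parameter name; one of `r paste(GAIT_PARAMETERS, collapse = ", ")`,
#'   or `"impulse"` to select the variant given by `impulse_variant`.
#' @param impulse_variant Which impulse enters asymmetries when
#'   `parameter = "impulse"`: `"imp_abs_pct_s"` (default) or `"imp_rel_pct"`.
#' @param quiet Suppress the skipped-day note.
#' @return Data frame with one row per (animal, day, pair): `animal_id`,
#'   `day_postop`, `pair` (`"hind"`/`"fore"`), `parameter`, `x_ipsi`,
#'   `x_contra`, `asymmetry_pct`, `flagged`.
#' @export
asymmetry_series <- function(summaries, parameter,
                             impulse_variant = c("imp_abs_pct_s", "imp_rel_pct"),
                             quiet = FALSE) {
  impulse_variant <- match.arg(impulse_variant)
  if (identical(parameter, "impulse")) parameter <- impulse_variant
  if (!parameter %in% GAIT_PARAMETERS)
    stop_gaitrec(sprintf("unknown parameter '%s'", parameter), "gaitrec_validation")
  s <- summaries[summaries$parameter == parameter, ]
  pairs <- list(hind = c("IH", "CH"), fore = c("IF", "CF"))
  rows <- list()
  skipped <- 0L
  for (a in unique(s$animal_id)) {
    sa <- s[s$animal_id == a, ]
    for (d in sort(unique(sa$day_postop))) {
      sd_ <- sa[sa$day_postop == d, ]
      for (pn in names(pairs)) {
        xi <- sd_$mean[sd_$limb == pairs[[pn]][1]]
        xc <- sd_$mean[sd_$limb == pairs[[pn]][2]]
        if (length(xi) != 1L || length(xc) != 1L) {
          skipped <- skipped + 1L
          next
        }
        flagged <- (xi + xc) == 0
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = a, day_postop = d, pair = pn, parameter = parameter,
          x_ipsi = xi, x_contra = xc,
          asymmetry_pct = if (flagged) NA_real_ else asymmetry_index(xi, xc),
          flagged = flagged)
      }
    }
  }
  if (skipped && !quiet)
    message(sprintf("asymmetry_series: %d animal-day pair(s) skipped (limb missing)",
                    skipped))
  if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE))) else
    data.frame(animal_id = character(), day_postop = numeric(),
               pair = character(), parameter = character(),
               x_ipsi = numeric(), x_contra = numeric(),
               asymmetry_pct = numeric(), flagged = logical())
}
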