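#' Compute body-weight-normalized gait parameters for one stance phase
#'
#' Definitions (g = 9.81 m/s^2, `BW` the body weight in kg, `F` the phase's
#' force samples in N, `A` the trapezoidal integral of `F` over the phase):
#' \itemize{
#'   \item `grf_peak_pct = max(F) / (BW g) * 100`,
#'   \item `grf_mean_pct = A / (t_c BW g) * 100` (the stance time-average),
#'   \item `t_c` from the sample count on the uniform grid,
#'   \item `imp_rel_pct = A / (t_c BW g) * 100`, the impulse normalized by body
#'     weight and contact time — by construction identical to `grf_mean_pct`,
#'     an identity the test suite asserts,
#'   \item `imp_abs_pct_s = A / (BW g) * 100`, the impulse normalized by body
#'     weight only (%BW·s).
#' }
#' Both impulse variants are provided because either convention appears in
#' force-platform work; downstream functions take an `impulse_variant` switch
#' (asymmetries default to the absolute variant, trajectories to the relative
#' one).
#'
#' @param forces Numeric vector of the phase's force samples (N), including
#'   the bounding baseline samples.
#' @param body_weight Body weight in kg (> 0).
#' @param sampling_rate Sampling rate in Hz.
#' @return One-row data frame with the five parameters.
#' @export
compute_parameters <- function(forces, body_weight, sampling_rate) {
  if (length(forces) < 2L)
    stop_gaitrec("a stance phase needs at least 2 samples", "gaitrec_contract")
  if (body_weight <= 0)
    stop_gaitrec("body_weight must be positive", "gaitrec_contract")
  n <- length(forces)
  t_c <- (n - 1) / sampling_rate
  bwg <- body_weight * GRAVITY
  area <- (sum(forces) - (forces[1] + forces[n]) / 2) / sampling_rate
  mean_pct <- area / t_c / bwg * 100
  data.frame(grf_peak_pct = max(forces) / bwg * 100,
             grf_mean_pct = mean_pct,
             t_c = t_c,
             imp_rel_pct = mean_pct,
             imp_abs_pct_s = area / bwg * 100)
}

#' Gait parameters for all valid phases of a segmentation
#'
#' @param phases A filtered `stance_phases` frame (see
#'   [apply_inclusion_filters()]).
#' @param valid_only Drop excluded phases (default TRUE).
#' @return Data frame with one row per phase: metadata columns plus the five
#'   gait parameters.
#' @export
phase_parameters <- function(phases, valid_only = TRUE) {
  stopifnot(inherits(phases, "stance_phases"))
  forces <- attr(phases, "forces")
  fs <- attr(phases, "sampling_rate")
  bw <- attr(phases, "body_weight")
  keep <- if (valid_only) which(phases$valid %in% TRUE) else seq_len(nrow(phases))
  if (!length(keep)) {
    out <- cbind(phases[0, c("animal_id", "limb", "day_postop", "session_id",
                             "phase")],
                 compute_parameters(c(0, 1), 1, 1)[0, ])
    return(out)
  }
  pars <- do.call(rbind, lapply(keep, function(i)
    compute_parameters(forces[[i]], bw, fs)))
  cbind(phases[keep, c("animal_id", "limb", "day_postop", "session_id",
                       "phase")],
        pars, row.names = NULL)
}

#' Aggregate per-phase parameters to daily summaries
#'
#' The unit of analysis of the monitoring protocol is the daily average: per
#' animal, limb and day, mean and sample standard deviation (n - 1
#' denominator) of each parameter over the session's valid phases. Groups with
#' a single phase report `sd = 0` with a caution message.
#'
#' @param parameters Per-phase parameter frame from [phase_parameters()],
#'   with columns `animal_id`, `limb`, `day_postop` plus the parameters.
#' @param quiet Suppress the single-phase caution (default FALSE).
#' @return Long-format data frame of class `daily_summary`: `animal_id`,
#'   `limb`, `day_postop`, `parameter`, `mean`, `sd`, `n_phases`. Empty input
#'   yields an empty frame.
#' @export
aggregate_daily <- function(parameters, quiet = FALSE) {
  cols <- intersect(GAIT_PARAMETERS, names(parameters))
  out <- data.frame(animal_id = character(), limb = character(),
                    day_postop = integer(), parameter = character(),
                    mean = numeric(), sd = numeric(), n_phases = integer())
  if (NROW(parameters)) {
    key <- interaction(parameters$animal_id, parameters$limb,
                       parameters$day_postop, drop = TRUE)
    groups <- split(parameters, key)
    singles <- 0L
    rows <- lapply(groups, function(g) {
      n <- nrow(g)
      if (n == 1L) singles <<- singles + 1L
      do.call(rbind, lapply(cols, function(p) data.frame(
        animal_id = g$animal_id[1], limb = g$limb[1],
        day_postop = g$day_postop[1], parameter = p,
        mean = mean(g[[p]]), sd = if (n > 1L) stats::sd(g[[p]]) else 0,
        n_phases = n)))
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out <- out[order(out$animal_id, out$limb, out$day_postop, out$parameter), ]
    rownames(out) <- NULL
    if (singles && !quiet)
      message(sprintf("aggregate_daily: %d group(s) with a single phase report sd = 0",
                      singles))
  }
  class(out) <- c("daily_summary", "data.frame")
  out
}

#' Run the full pipeline on a cohort
#'
#' Segmentation, inclusion filtering, per-phase parameter extraction and daily
#' aggregation for every recording of a simulated (or read-from-disk) cohort.
#'
#' @param cohort A `gait_cohort` from [simulate_cohort()], or a list with a
#'   `recordings` element.
#' @param config A [seg_config()].
#' @param quiet Passed to [aggregate_daily()].
#' @return An object of class `gait_analysis`: list with `phases` (all phases,
#'   flags included), `parameters` (per valid phase) and `daily`
#'   (`daily_summary`).
#' @export
analyze_cohort <- function(cohort, config = seg_config(), quiet = FALSE) {
  recs <- if (inherits(cohort, "gait_cohort") || is.list(cohort))
    cohort$recordings else cohort
  seg <- lapply(recs, segment_recording, config = config)
  pars <- do.call(rbind, c(lapply(seg, phase_parameters),
                           list(make.row.names = FALSE)))
  phases <- do.call(rbind, c(lapply(seg, function(p) as.data.frame(p)),
                             list(make.row.names = FALSE)))
  structure(list(phases = phases, parameters = pars,
                 daily = aggregate_daily(pars, quiet = quiet)),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf("<gait_analysis> %d phases (%d valid) -> %d daily summaries\n",
              nrow(x$phases), sum(x$phases$valid %in% TRUE),
              nrow(x$daily) / length(unique(x$daily$parameter))))
  invisible(x)
}
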