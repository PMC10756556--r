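#' Segmentation configuration
#'
#' The stance-detection rule follows the force trace from the time-point at
#' which the force rises off the baseline until it returns to baseline. Real
#' platforms have a noise floor, so "zero" is an `onset_threshold` gate
#' (default 5 N, about 1 %BW of a 55 kg sheep and well below even acutely lame
#' peak forces). The amble-speed inclusion criterion of the study protocol
#' (stances walked above or below 2-4 km/h were discarded) cannot be measured
#' from a single platform; a contact-time window `t_c_bounds` stands in for it.
#'
#' @param onset_threshold Baseline noise gate in N (>= 0).
#' @param min_peak Minimal peak force in N for a phase to count as a stance
#'   (gates out transient blips).
#' @param t_c_bounds Inclusive contact-time window in seconds, ordered.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(onset_threshold = 5, min_peak = 20,
                       t_c_bounds = c(0.15, 1.20)) {
  if (onset_threshold < 0)
    stop_gaitrec("onset_threshold must be >= 0", "gaitrec_validation")
  if (length(t_c_bounds) != 2L || t_c_bounds[1] > t_c_bounds[2])
    stop_gaitrec("t_c_bounds must be an ordered pair", "gaitrec_validation")
  structure(list(onset_threshold = onset_threshold, min_peak = min_peak,
                 t_c_bounds = t_c_bounds),
            class = "seg_config")
}

#' Detect stance phases in a force recording
#'
#' A stance phase is a maximal run of samples strictly above the onset
#' threshold, extended by one bounding sub-threshold sample on each side: the
#' phase spans from the sample at which the force increase is first recorded
#' (the last baseline sample before the supra-threshold run) to the sample at
#' which the force has returned to baseline. Contact time is
#' `(end_index - start_index) / sampling_rate`, computed on the uniform sample
#' grid, so a noise-free synthetic template is recovered with its nominal
#' duration exactly. Runs touching the first or last sample lack a bounding
#' baseline sample and are flagged `edge_truncated`. Negative samples (sensor
#' noise) are clipped to zero. Indices are 1-based and inclusive.
#'
#' @param recording A [force_recording()].
#' @param config A [seg_config()].
#' @return A data frame of class `stance_phases`, one row per phase:
#'   `phase`, `start_index`, `end_index`, `start_s`, `end_s`, `t_c`, `peak_N`,
#'   `valid`, `exclusion_reason`, plus the recording metadata; the per-phase
#'   force vectors are kept in the `"forces"` attribute. An empty recording
#'   yields zero rows.
#' @export
detect_stance_phases <- function(recording, config = seg_config()) {
  stopifnot(inherits(recording, "force_recording"),
            inherits(config, "seg_config"))
  f <- pmax(recording$force, 0)
  fs <- recording$sampling_rate
  n <- length(f)
  above <- f > config$onset_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  rows <- vector("list", length(runs))
  forces <- vector("list", length(runs))
  for (j in seq_along(runs)) {
    k <- runs[j]
    i0 <- starts[k] - 1L   # last baseline sample before onset
    i1 <- ends[k] + 1L     # first baseline sample after return
    edge <- i0 < 1L || i1 > n
    i0 <- max(i0, 1L)
    i1 <- min(i1, n)
    seg <- f[i0:i1]
    rows[[j]] <- data.frame(
      phase = j, start_index = i0, end_index = i1,
      start_s = (i0 - 1L) / fs, end_s = (i1 - 1L) / fs,
      t_c = (i1 - i0) / fs, peak_N = max(seg),
      valid = NA, exclusion_reason = if (edge) "edge_truncated" else "none")
    forces[[j]] <- seg
  }
  ph <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phase = integer(), start_index = integer(), end_index = integer(),
               start_s = numeric(), end_s = numeric(), t_c = numeric(),
               peak_N = numeric(), valid = logical(),
               exclusion_reason = character())
  if (nrow(ph)) {
    ph$animal_id <- recording$animal_id
    ph$limb <- recording$limb
    ph$day_postop <- recording$day_postop
    ph$session_id <- recording$session_id
  }
  attr(ph, "forces") <- forces
  attr(ph, "sampling_rate") <- fs
  attr(ph, "body_weight") <- recording$body_weight
  class(ph) <- c("stance_phases", "data.frame")
  ph
}

#' Apply the stance inclusion filters
#'
#' Marks each detected phase valid if and only if it is not edge-truncated,
#' its peak force reaches `min_peak`, and its contact time lies inside
#' `t_c_bounds` (the stand-in for the amble-speed criterion). Exclusion
#' reasons are recorded as `edge_truncated`, `below_threshold_peak`,
#' `too_short` or `too_long`; counts per reason are attached as the
#' `"exclusion_counts"` attribute.
#'
#' @param phases A `stance_phases` frame from [detect_stance_phases()].
#' @param config A [seg_config()].
#' @return `phases` with `valid` and `exclusion_reason` filled in.
#' @export
apply_inclusion_filters <- function(phases, config = seg_config()) {
  stopifnot(inherits(phases, "stance_phases"))
  if (nrow(phases)) {
    reason <- phases$exclusion_reason
    reason[reason == "none" & phases$peak_N < config$min_peak] <- "below_threshold_peak"
    reason[reason == "none" & phases$t_c < config$t_c_bounds[1]] <- "too_short"
    reason[reason == "none" & phases$t_c > config$t_c_bounds[2]] <- "too_long"
    phases$exclusion_reason <- reason
    phases$valid <- reason == "none"
  }
  attr(phases, "exclusion_counts") <-
    table(factor(phases$exclusion_reason,
                 levels = c("none", "edge_truncated", "below_threshold_peak",
                            "too_short", "too_long")))
  phases
}

#' Segment a recording and filter in one call
#'
#' @param recording A [force_recording()].
#' @param config A [seg_config()].
#' @return A filtered `stance_phases` frame.
#' @export
segment_recording <- function(recording, config = seg_config()) {
  apply_inclusion_filters(detect_stance_phases(recording, config), config)
}
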