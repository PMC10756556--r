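#' Piecewise-linear recovery trajectory parameters
#'
#' Describes the expected longitudinal evolution of one gait parameter for one
#' limb: the animal starts walking at `t_start` (days post-surgery) at the
#' post-operative value `v_postop`, evolves linearly to
#' `v_control * (1 +/- residual_frac)` at `t_recovery`, and stays constant
#' thereafter. Compensating limbs use the same form with `v_postop > v_control`
#' (an elevation decaying back to control).
#'
#' @param v_postop Parameter value immediately after the latency period.
#' @param v_control Healthy reference value (> 0).
#' @param t_start First walking day post-surgery (default 7, the latency and
#'   recovery period of the study design).
#' @param t_recovery Day of full normalization (> `t_start`).
#' @param residual_frac Persistent fractional deviation from control after
#'   `t_recovery` (default 0). Sign follows the deviation direction of
#'   `v_postop` (deficit stays a deficit, elevation an elevation).
#'
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(v_postop, v_control, t_start = 7,
                              t_recovery, residual_frac = 0) {
  if (v_control <= 0) stop_gaitrec("v_control must be > 0", "gaitrec_validation")
  if (t_recovery <= t_start)
    stop_gaitrec("t_recovery must exceed t_start", "gaitrec_validation")
  structure(list(v_postop = v_postop, v_control = v_control,
                 t_start = t_start, t_recovery = t_recovery,
                 residual_frac = residual_frac),
            class = "trajectory_params")
}

#' Expected parameter value on a given day
#'
#' @param params A [trajectory_params()].
#' @param day Day post-surgery (>= `t_start`; querying before the animal walks
#'   is an error).
#' @return The expected value (vectorized over `day`).
#' @examples
#' tr <- trajectory_params(23, 42, t_start = 0, t_recovery = 160)
#' trajectory_value(tr, 80)  # 32.5
#' @export
trajectory_value <- function(params, day) {
  stopifnot(inherits(params, "trajectory_params"))
  if (any(day < params$t_start))
    stop_gaitrec(sprintf("day %g precedes first walking day %g",
                         min(day), params$t_start), "gaitrec_query")
  dir <- sign(params$v_postop - params$v_control)
  v_end <- params$v_control * (1 + dir * params$residual_frac)
  frac <- pmin(1, (day - params$t_start) / (params$t_recovery - params$t_start))
  params$v_postop + frac * (v_end - params$v_postop)
}

#' Healthy control reference values
#'
#' Package defaults for a healthy adult sheep walking at amble: hindlimb peak
#' GRF 42 %BW, stance-average 28 %BW, contact time 0.58 s; forelimb
#' stance-average 45 %BW, contact time 0.52 s. The forelimb peak (59 %BW,
#' yielding a 45/59 mean/peak ratio attainable by the template family) is a
#' package calibration choice; see the methods vignette.
#'
#' @return Nested list with `hind` and `fore` components, each holding
#'   `grf_peak_pct`, `grf_mean_pct`, `t_c`.
#' @export
control_reference <- function() {
  list(hind = list(grf_peak_pct = 42, grf_mean_pct = 28, t_c = 0.58),
       fore = list(grf_peak_pct = 59, grf_mean_pct = 45, t_c = 0.52))
}

#' Default post-operative recovery trajectories
#'
#' The package defaults emulating the study cohort after scaffold implantation
#' of the right hind metatarsus (operated limb `IH`):
#' \itemize{
#'   \item `IH` peak GRF 23 -> 42 %BW over days 7 -> 160 (a gain of 19 %BW,
#'     i.e. ~3.8 %BW/month); contact time 0.28 -> 0.58 s by day 200; stance
#'     shape a single hump (`dip_depth` 0) whose sharpness relaxes from 2
#'     (raised-cosine, stance-average 11.5 %BW at day 7) to 1 by day 160, after
#'     which the healthy M-shape template is used.
#'   \item `CH` compensatory elevation: peak 59.6 -> 42 %BW (control + 17.59),
#'     stance-average 38 -> 28 %BW, contact time 0.63 -> 0.58 s (control
#'     + 0.05).
#'   \item `IF`/`CF` peak elevated by 11.2 / 21.7 %BW over the forelimb
#'     control, decaying to control by day 160 at the control mean/peak ratio;
#'     contact times 0.57 -> 0.52 s by day 200.
#' }
#'
#' @param t_start First walking day (default 7).
#' @param t_force_recovery Day the force parameters normalize (default 160).
#' @param t_tc_recovery Day the contact times normalize (default 200).
#' @return Nested list: per limb, `trajectory_params` for `grf_peak_pct` and
#'   `t_c`, plus `grf_mean_pct` where the mean is calibrated independently
#'   (`CH`), and shape settings.
#' @export
default_trajectories <- function(t_start = 7, t_force_recovery = 160,
                                 t_tc_recovery = 200) {
  ctrl <- control_reference()
  fore_ratio <- ctrl$fore$grf_mean_pct / ctrl$fore$grf_peak_pct
  list(
    IH = list(
      grf_peak_pct = trajectory_params(23, ctrl$hind$grf_peak_pct,
                                       t_start, t_force_recovery),
      t_c = trajectory_params(0.28, ctrl$hind$t_c, t_start, t_tc_recovery),
      sharpness = trajectory_params(2, 1, t_start, t_force_recovery),
      shape = "lame"),
    CH = list(
      grf_peak_pct = trajectory_params(ctrl$hind$grf_peak_pct + 17.59,
                                       ctrl$hind$grf_peak_pct,
                                       t_start, t_force_recovery),
      grf_mean_pct = trajectory_params(38, ctrl$hind$grf_mean_pct,
                                       t_start, t_force_recovery),
      t_c = trajectory_params(ctrl$hind$t_c + 0.05, ctrl$hind$t_c,
                              t_start, t_tc_recovery),
      shape = "m_shape"),
    IF = list(
      grf_peak_pct = trajectory_params(ctrl$fore$grf_peak_pct + 11.2,
                                       ctrl$fore$grf_peak_pct,
                                       t_start, t_force_recovery),
      t_c = trajectory_params(ctrl$fore$t_c + 0.05, ctrl$fore$t_c,
                              t_start, t_tc_recovery),
      mean_ratio = fore_ratio,
      shape = "m_shape"),
    CF = list(
      grf_peak_pct = trajectory_params(ctrl$fore$grf_peak_pct + 21.7,
                                       ctrl$fore$grf_peak_pct,
                                       t_start, t_force_recovery),
      t_c = trajectory_params(ctrl$fore$t_c + 0.05, ctrl$fore$t_c,
                              t_start, t_tc_recovery),
      mean_ratio = fore_ratio,
      shape = "m_shape"))
}

# control templates per limb class, dip depth calibrated on the deep branch
# from the control mean/peak ratios
control_templates <- function() {
  hit <- .gaitrec_cache$control_templates
  if (!is.null(hit)) return(hit)
  ctrl <- control_reference()
  d_hind <- solve_dip_depth(ctrl$hind$grf_mean_pct / ctrl$hind$grf_peak_pct,
                            branch = "deep")
  d_fore <- solve_dip_depth(ctrl$fore$grf_mean_pct / ctrl$fore$grf_peak_pct,
                            branch = "deep")
  out <- list(
    IH = template_params(ctrl$hind$grf_peak_pct, ctrl$hind$t_c, d_hind),
    IF = template_params(ctrl$fore$grf_peak_pct, ctrl$fore$t_c, d_fore),
    CH = template_params(ctrl$hind$grf_peak_pct, ctrl$hind$t_c, d_hind),
    CF = template_params(ctrl$fore$grf_peak_pct, ctrl$fore$t_c, d_fore))
  .gaitrec_cache$control_templates <- out
  out
}

# expected (noise-free) template for one limb of an operated animal on a given
# day; `animal_factor` scales the deviation-from-control of every trajectory
operated_template <- function(limb, day, traj = default_trajectories(),
                              animal_factor = 1) {
  tr <- traj[[limb]]
  ctrl <- control_templates()[[limb]]
  adj <- function(tp) {
    v <- trajectory_value(tp, day)
    tp$v_control + animal_factor * (v - tp$v_control)
  }
  peak <- adj(tr$grf_peak_pct)
  t_c <- adj(tr$t_c)
  if (identical(tr$shape, "lame") && day < tr$sharpness$t_recovery) {
    p <- trajectory_value(tr$sharpness, day)
    template_params(peak, t_c, dip_depth = 0, sharpness = p)
  } else if (!is.null(tr$grf_mean_pct)) {
    m <- adj(tr$grf_mean_pct)
    d <- solve_dip_depth(min(m / peak, 0.775), branch = "deep")
    template_params(peak, t_c, dip_depth = d)
  } else if (!is.null(tr$mean_ratio)) {
    d <- solve_dip_depth(tr$mean_ratio, branch = "deep")
    template_params(peak, t_c, dip_depth = d)
  } else {
    template_params(peak, t_c, dip_depth = ctrl$dip_depth)
  }
}
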