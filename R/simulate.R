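#' Cohort simulation configuration
#'
#' Defaults reproduce the study design: 8 operated animals, 3 non-operated
#' controls, weekly measurement sessions from day 7 (the post-surgical latency
#' and recovery period) to day 210, 7-10 stance phases recorded per limb and
#' session, body weight ~ Normal(57.90, 9.62^2) kg truncated at 30 kg, 5 %
#' between-step noise and 5 % between-animal trajectory heterogeneity.
#'
#' @param n_operated Number of operated animals (>= 0).
#' @param n_control Number of non-operated control animals (>= 0).
#' @param session_days Measurement days post-surgery, sorted ascending.
#' @param phases_min,phases_max Range of stance phases per limb and session.
#' @param noise_cv Between-step coefficient of variation of the lognormal
#'   multiplicative noise on peak force and contact time (>= 0).
#' @param animal_cv Between-animal CV of the mean-one lognormal factor applied
#'   to each animal's deviation from control (>= 0).
#' @param body_weight_mean,body_weight_sd Body-weight distribution (kg).
#' @param sampling_rate Platform sampling rate in Hz.
#' @param trajectories Trajectory set, see [default_trajectories()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_operated = 8, n_control = 3,
                          session_days = seq(7, 210, by = 7),
                          phases_min = 7, phases_max = 10,
                          noise_cv = 0.05, animal_cv = 0.05,
                          body_weight_mean = 57.90, body_weight_sd = 9.62,
                          sampling_rate = 50,
                          trajectories = default_trajectories()) {
  if (n_operated < 0 || n_control < 0 || n_operated + n_control < 1)
    stop_gaitrec("need at least one animal", "gaitrec_validation")
  if (is.unsorted(session_days))
    stop_gaitrec("session_days must be sorted ascending", "gaitrec_validation")
  if (noise_cv < 0 || animal_cv < 0)
    stop_gaitrec("noise CVs must be >= 0", "gaitrec_validation")
  if (phases_min < 1 || phases_max < phases_min)
    stop_gaitrec("invalid phases_per_session range", "gaitrec_validation")
  structure(list(n_operated = n_operated, n_control = n_control,
                 session_days = session_days,
                 phases_min = phases_min, phases_max = phases_max,
                 noise_cv = noise_cv, animal_cv = animal_cv,
                 body_weight_mean = body_weight_mean,
                 body_weight_sd = body_weight_sd,
                 sampling_rate = sampling_rate,
                 trajectories = trajectories),
            class = "cohort_config")
}

# mean-one lognormal draws with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one measurement session for a set of limbs
#'
#' Concatenates `n_phases` stance templates per limb, separated by zero-force
#' gaps drawn uniformly from `gap_range` (and padded at both ends), applying
#' independent mean-one lognormal factors with CV `noise_cv` to each phase's
#' peak force and contact time. Forces are converted from % body weight to
#' newtons with g = 9.81 m/s^2. The generator is reproducible: the result is a
#' pure function of the RNG state (use `set.seed()` or the `seed` argument).
#'
#' @param templates Named list of [template_params()], one per limb label.
#' @param n_phases Number of stance phases per limb (>= 1).
#' @param noise_cv Between-step coefficient of variation (>= 0).
#' @param body_weight Body weight in kg.
#' @param animal_id,day_postop,session_id Metadata copied to the recordings.
#' @param sampling_rate Sampling rate in Hz (default 50).
#' @param gap_range Zero-force gap duration range in seconds (>= 0.3 s).
#' @param seed Optional integer seed applied locally (RNG state restored on
#'   exit).
#'
#' @return Named list of [force_recording()]s with attribute `"truth"`: a data
#'   frame of per-phase ground truth (limb, phase index, onset/offset sample,
#'   nominal contact time, peak and mean %BW).
#' @export
simulate_session <- function(templates, n_phases = 8, noise_cv = 0.05,
                             body_weight = 57.9, animal_id = "A1",
                             day_postop = 0,
                             session_id = paste0(animal_id, "_d", day_postop),
                             sampling_rate = 50, gap_range = c(0.3, 0.6),
                             seed = NULL) {
  if (n_phases < 1) stop_gaitrec("n_phases must be >= 1", "gaitrec_validation")
  if (noise_cv < 0) stop_gaitrec("noise_cv must be >= 0", "gaitrec_validation")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  newton_per_pct <- body_weight * GRAVITY / 100
  out <- list()
  truth <- list()
  for (limb in names(templates)) {
    tp <- templates[[limb]]
    peak_f <- rlnorm_cv(n_phases, noise_cv)
    tc_f <- rlnorm_cv(n_phases, noise_cv)
    gaps <- stats::runif(n_phases + 1, gap_range[1], gap_range[2])
    force <- numeric(0)
    rows <- vector("list", n_phases)
    for (k in seq_len(n_phases)) {
      force <- c(force, numeric(round(gaps[k] * sampling_rate)))
      tpk <- tp
      tpk$peak_frac <- tp$peak_frac * peak_f[k]
      tpk$t_c <- tp$t_c * tc_f[k]
      pct <- stance_template(tpk, sampling_rate)
      n_tpl <- length(pct)
      onset <- length(force) + 1L               # sample where force leaves zero
      force <- c(force, pct * newton_per_pct)
      ratio <- (sum(pct) - (pct[1] + pct[n_tpl]) / 2) / (n_tpl - 1) /
        max(pct)                                 # measured-mean/peak of this phase
      rows[[k]] <- data.frame(
        limb = limb, phase = k, onset = onset, offset = onset + n_tpl - 1L,
        t_c = (n_tpl - 1) / sampling_rate,
        grf_peak_pct = max(pct), grf_mean_pct = ratio * max(pct))
    }
    force <- c(force, numeric(round(gaps[n_phases + 1] * sampling_rate)))
    out[[limb]] <- force_recording(force, sampling_rate, animal_id, limb,
                                   day_postop, body_weight, session_id)
    truth[[limb]] <- do.call(rbind, rows)
  }
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Simulate a longitudinal force-platform cohort
#'
#' Generates the full study structure: per operated animal, per session day and
#' limb, the expected noise-free template is derived from the recovery
#' trajectories ([default_trajectories()]; dip depth calibrated from the
#' mean/peak ratio via [solve_dip_depth()]) and a session of noisy stance
#' phases is synthesized with [simulate_session()]. Control animals use the
#' healthy control templates throughout. Body weight is drawn once per animal.
#' The result is a pure function of `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (applied locally; RNG state restored on exit).
#' @return An object of class `gait_cohort`: list with `recordings` (list of
#'   [force_recording()]), `manifest` (data frame), `truth` (per animal, limb
#'   and day: expected noise-free parameter values) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ctrl_tpl <- control_templates()
  animals <- c(
    if (config$n_operated > 0) sprintf("OP%02d", seq_len(config$n_operated)),
    if (config$n_control > 0) sprintf("CT%02d", seq_len(config$n_control)))
  operated <- grepl("^OP", animals)
  recordings <- list()
  manifest <- list()
  truth <- list()
  t_start <- if (config$n_operated > 0)
    config$trajectories$IH$grf_peak_pct$t_start else -Inf
  for (i in seq_along(animals)) {
    a <- animals[i]
    bw <- 0
    while (bw < 30)
      bw <- stats::rnorm(1, config$body_weight_mean, config$body_weight_sd)
    afac <- rlnorm_cv(1, config$animal_cv)
    for (day in config$session_days) {
      if (operated[i] && day < t_start) {
        warning(sprintf("skipping %s day %g: before first walking day %g",
                        a, day, t_start))
        next
      }
      tpls <- if (operated[i]) {
        stats::setNames(lapply(LIMB_LABELS, function(l)
          operated_template(l, day, config$trajectories, afac)), LIMB_LABELS)
      } else ctrl_tpl
      n_ph <- if (config$phases_max > config$phases_min)
        sample(config$phases_min:config$phases_max, 1) else config$phases_min
      ses <- simulate_session(tpls, n_phases = n_ph,
                              noise_cv = config$noise_cv, body_weight = bw,
                              animal_id = a, day_postop = day,
                              sampling_rate = config$sampling_rate)
      for (l in names(ses)) {
        recordings[[length(recordings) + 1L]] <- ses[[l]]
        manifest[[length(manifest) + 1L]] <- data.frame(
          animal_id = a, limb = l, day_postop = day, body_weight_kg = bw,
          session_id = paste0(a, "_d", day), operated = operated[i])
        tp <- tpls[[l]]
        ratio <- template_mean_peak_ratio(tp$dip_depth, tp$hump_asymmetry,
                                          tp$sharpness)
        truth[[length(truth) + 1L]] <- data.frame(
          animal_id = a, limb = l, day_postop = day, operated = operated[i],
          n_phases = n_ph, grf_peak_pct = tp$peak_frac,
          grf_mean_pct = ratio * tp$peak_frac, t_c = tp$t_c,
          imp_abs_pct_s = ratio * tp$peak_frac * tp$t_c)
      }
    }
  }
  structure(list(recordings = recordings,
                 manifest = do.call(rbind, manifest),
                 truth = do.call(rbind, truth),
                 config = config),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<gait_cohort> %d recordings: %d animals (%d operated), days %g-%g\n",
              nrow(m), length(unique(m$animal_id)),
              length(unique(m$animal_id[m$operated])),
              min(m$day_postop), max(m$day_postop)))
  invisible(x)
}
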