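#' Stance-curve template parameters
#'
#' Parameters of the synthetic vertical-GRF stance waveform. The waveform
#' family is a sine product
#' \deqn{F(t) \propto \sin^p(\pi t/t_c)\,[1 - d\,\sin^2(\pi t/t_c)]\,
#'       [1 + (a-1)\,t/t_c],}
#' rescaled so its sampled maximum equals `peak_frac` exactly. With dip depth
#' `d = 0` and sharpness `p = 1` it is a half-sine; `d > 1/3` produces the
#' double-peaked M-shape of a healthy hindlimb with a mid-stance valley;
#' `p > 1` produces the narrow single-hump bump of an acutely lame limb whose
#' stance-average force is well below the half-sine value. `a` tilts the two
#' humps (second vs first).
#'
#' @param peak_frac Target peak force as % of body weight (> 0).
#' @param t_c Contact time in seconds (> 0).
#' @param dip_depth Mid-stance valley depth `d` in `[0, 1)`; 0 = single hump.
#' @param hump_asymmetry Relative height of the second hump vs the first,
#'   in `(0, 2)`; 1 = symmetric.
#' @param sharpness Exponent `p >= 1` of the base hump; 1 = half-sine (healthy),
#'   2 = raised-cosine (acutely lame, "punctual" contact).
#'
#' @return An object of class `template_params`.
#' @seealso [stance_template()], [solve_dip_depth()]
#' @export
template_params <- function(peak_frac, t_c, dip_depth = 0,
                            hump_asymmetry = 1, sharpness = 1) {
  if (peak_frac <= 0) stop_gaitrec("peak_frac must be > 0", "gaitrec_validation")
  if (t_c <= 0) stop_gaitrec("t_c must be > 0", "gaitrec_validation")
  if (dip_depth < 0 || dip_depth >= 1)
    stop_gaitrec("dip_depth must lie in [0, 1)", "gaitrec_validation")
  if (hump_asymmetry <= 0 || hump_asymmetry >= 2)
    stop_gaitrec("hump_asymmetry must lie in (0, 2)", "gaitrec_validation")
  if (sharpness < 1) stop_gaitrec("sharpness must be >= 1", "gaitrec_validation")
  structure(list(peak_frac = peak_frac, t_c = t_c, dip_depth = dip_depth,
                 hump_asymmetry = hump_asymmetry, sharpness = sharpness),
            class = "template_params")
}

# unscaled waveform on x in [0, pi]; sin clamped at 0 so fractional sharpness
# exponents survive the tiny negative rounding of sin(pi*n/n)
template_shape <- function(x, dip_depth, hump_asymmetry = 1, sharpness = 1) {
  s <- pmax(sin(x), 0)
  s^sharpness * (1 - dip_depth * s^2) * (1 + (hump_asymmetry - 1) * x / pi)
}

#' Sample a stance-curve template
#'
#' Evaluates the waveform of [template_params()] on the uniform grid
#' `t = 0, 1/fs, ..., t_c` (both endpoints included, where the force is zero)
#' and rescales it so the maximum of the sampled sequence equals `peak_frac`
#' exactly. Values are in % body weight.
#'
#' @param params A [template_params()].
#' @param sampling_rate Sampling rate in Hz; the contact must span at least
#'   8 samples, otherwise a resolution error is raised.
#'
#' @return Numeric vector of force values (% BW), zero at both endpoints.
#' @examples
#' f <- stance_template(template_params(42, 0.58, dip_depth = 0.84), 50)
#' max(f)  # exactly 42
#' @export
stance_template <- function(params, sampling_rate) {
  stopifnot(inherits(params, "template_params"))
  n <- round(sampling_rate * params$t_c)
  if (n + 1 < 8)
    stop_gaitrec(sprintf(
      "contact time %.3g s spans only %d samples at %g Hz (need >= 8)",
      params$t_c, n + 1, sampling_rate), "gaitrec_resolution")
  x <- pi * (0:n) / n
  f <- template_shape(x, params$dip_depth, params$hump_asymmetry, params$sharpness)
  f / max(f) * params$peak_frac
}

# trapezoidal time-average / max of the sampled waveform; grid fine enough
# that the ratio is within ~1e-5 of the continuous value
template_mean_peak_ratio <- function(dip_depth, hump_asymmetry = 1,
                                     sharpness = 1, n_grid = 800) {
  x <- seq(0, pi, length.out = n_grid + 1)
  f <- template_shape(x, dip_depth, hump_asymmetry, sharpness)
  mean_f <- (sum(f) - (f[1] + f[n_grid + 1]) / 2) / n_grid
  mean_f / max(f)
}

#' Calibrate the valley depth from a target mean/peak ratio
#'
#' Finds the dip depth `d` such that the template's numeric mean/peak force
#' ratio equals `target_ratio` (within 1e-4). The ratio is not monotone in `d`
#' over the whole family: it rises from \eqn{2/\pi \approx 0.637} at `d = 0` to
#' about 0.780 at `d = 0.5` and then falls towards 0.551 as `d` approaches 1.
#' The root search therefore runs on one monotone branch: `"flat"` (shallow
#' valley, `d` below the ratio's argmax; contains the half-sine and gives
#' `d = 0` for target `2/pi`) or `"deep"` (pronounced M-shape, `d` above the
#' argmax; the branch used to calibrate healthy M-shaped limbs, e.g. a 28/42
#' mean/peak control ratio gives `d` of about 0.84).
#'
#' @param target_ratio Target mean/peak ratio, in (0, 1).
#' @param branch `"flat"` (default) or `"deep"`; see Details.
#' @param hump_asymmetry,sharpness Fixed shape parameters of the family.
#' @return The dip depth `d`.
#' @examples
#' solve_dip_depth(2 / pi)                    # 0 (half-sine)
#' solve_dip_depth(28 / 42, branch = "deep")  # ~0.84, M-shaped
#' @export
solve_dip_depth <- function(target_ratio, branch = c("flat", "deep"),
                            hump_asymmetry = 1, sharpness = 1) {
  branch <- match.arg(branch)
  key <- sprintf("%.8f|%s|%g|%g", target_ratio, branch, hump_asymmetry, sharpness)
  hit <- .gaitrec_cache$dip[[key]]
  if (!is.null(hit)) {
    if (inherits(hit, "condition")) stop(hit)
    return(hit)
  }
  res <- tryCatch(solve_dip_depth_impl(target_ratio, branch, hump_asymmetry,
                                       sharpness),
                  gaitrec_domain = function(e) e)
  .gaitrec_cache$dip[[key]] <- res
  if (inherits(res, "condition")) stop(res)
  res
}

solve_dip_depth_impl <- function(target_ratio, branch,
                                 hump_asymmetry = 1, sharpness = 1) {
  if (target_ratio <= 0 || target_ratio >= 1)
    stop_gaitrec("target_ratio must lie in (0, 1)", "gaitrec_validation")
  rf <- function(d) template_mean_peak_ratio(d, hump_asymmetry, sharpness)
  skey <- sprintf("argmax|%g|%g", hump_asymmetry, sharpness)
  d_star <- .gaitrec_cache$dip[[skey]]
  if (is.null(d_star)) {
    d_star <- stats::optimize(rf, c(0, 0.9995), maximum = TRUE, tol = 1e-8)$maximum
    .gaitrec_cache$dip[[skey]] <- d_star
  }
  iv <- if (branch == "deep") c(d_star, 0.9995) else c(0, d_star)
  rng <- sort(c(rf(iv[1]), rf(iv[2])))
  if (target_ratio < rng[1] - 1e-6 || target_ratio > rng[2] + 1e-6)
    stop_gaitrec(sprintf(
      "target mean/peak ratio %.4f not achievable on the '%s' branch (achievable: %.4f-%.4f)",
      target_ratio, branch, rng[1], rng[2]), "gaitrec_domain")
  target_ratio <- min(max(target_ratio, rng[1]), rng[2])
  if (abs(rf(iv[1]) - target_ratio) < 2e-6) return(iv[1])
  if (abs(rf(iv[2]) - target_ratio) < 2e-6) return(iv[2])
  stats::uniroot(function(d) rf(d) - target_ratio, iv, tol = 1e-8)$root
}
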