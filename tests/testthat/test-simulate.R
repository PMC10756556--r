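ctrl_tpls <- function() gaitrec:::control_templates()

test_that("a noise-free session yields identical phases that segmentation recovers exactly", {
  ses <- simulate_session(ctrl_tpls()["IH"], n_phases = 5, noise_cv = 0,
                          body_weight = 57.9, seed = 1)
  truth <- attr(ses, "truth")
  ph <- segment_recording(ses$IH)
  expect_equal(nrow(ph), 5)
  expect_true(all(ph$valid))
  expect_equal(ph$t_c, truth$t_c)                   # nominal duration, exact
  expect_equal(ph$start_index, truth$onset)         # template's zero endpoints
  expect_equal(ph$end_index, truth$offset)          # are the phase boundaries
  pars <- phase_parameters(ph)
  expect_equal(diff(range(pars$grf_peak_pct)), 0)       # all phases identical
  expect_equal(pars$grf_peak_pct, rep(42, 5))
})

test_that("sessions are bit-identical under a fixed seed and differ across seeds", {
  a <- simulate_session(ctrl_tpls(), n_phases = 4, seed = 42)
  b <- simulate_session(ctrl_tpls(), n_phases = 4, seed = 42)
  c <- simulate_session(ctrl_tpls(), n_phases = 4, seed = 43)
  expect_identical(a$IH$force, b$IH$force)
  expect_identical(a$CF$force, b$CF$force)
  expect_false(identical(a$IH$force, c$IH$force))
})

test_that("between-step noise reproduces the requested coefficient of variation", {
  ses <- simulate_session(ctrl_tpls()["IH"], n_phases = 1000, noise_cv = 0.05,
                          seed = 5)
  peaks <- attr(ses, "truth")$grf_peak_pct
  cv <- stats::sd(peaks) / mean(peaks)
  expect_gt(cv, 0.045)
  expect_lt(cv, 0.055)
})

test_that("cohort generation is a pure function of (config, seed) with the expected structure", {
  cfg <- cohort_config(n_operated = 1, n_control = 1,
                       session_days = c(7, 21, 35),
                       phases_min = 3, phases_max = 3)
  a <- simulate_cohort(cfg, seed = 9)
  b <- simulate_cohort(cfg, seed = 9)
  c <- simulate_cohort(cfg, seed = 10)
  # 2 animals x 4 limbs x 3 days
  expect_equal(nrow(a$manifest), 24)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$recordings[[5]]$force, b$recordings[[5]]$force)
  # different seed: same structure, different forces
  expect_identical(dim(c$manifest), dim(a$manifest))
  expect_identical(c$manifest[c("animal_id", "limb", "day_postop")],
                   a$manifest[c("animal_id", "limb", "day_postop")])
  expect_false(identical(a$recordings[[1]]$force, c$recordings[[1]]$force))
})

test_that("sessions before the first walking day are skipped with a warning", {
  cfg <- cohort_config(n_operated = 1, n_control = 0, session_days = c(2, 7),
                       phases_min = 3, phases_max = 3)
  expect_warning(co <- simulate_cohort(cfg, seed = 1), "before first walking day")
  expect_equal(unique(co$manifest$day_postop), 7)
})

test_that("a no-noise cohort's pipeline daily means equal the generator trajectories exactly", {
  cfg <- cohort_config(n_operated = 1, n_control = 0,
                       session_days = c(7, 56, 105), phases_min = 4,
                       phases_max = 4, noise_cv = 0, animal_cv = 0,
                       body_weight_sd = 0)
  co <- simulate_cohort(cfg, seed = 3)
  an <- analyze_cohort(co, quiet = TRUE)
  d <- an$daily
  for (l in LIMB_LABELS) for (day in c(7, 56, 105)) {
    tru <- co$truth[co$truth$limb == l & co$truth$day_postop == day, ]
    got <- d[d$limb == l & d$day_postop == day, ]
    expect_equal(got$mean[got$parameter == "grf_peak_pct"], tru$grf_peak_pct,
                 tolerance = 1e-9)
    # nominal durations are rounded to the 50 Hz grid (at most one sample off)
    expect_equal(got$mean[got$parameter == "t_c"], tru$t_c, tolerance = 0.02)
    expect_equal(got$mean[got$parameter == "grf_mean_pct"], tru$grf_mean_pct,
                 tolerance = 0.005)
    expect_equal(got$mean[got$parameter == "grf_mean_pct"],
                 got$mean[got$parameter == "imp_rel_pct"], tolerance = 1e-12)
  }
})

test_that("parameter recovery: noisy daily means track trajectories within 3%", {
  cfg <- cohort_config(n_operated = 1, n_control = 0,
                       session_days = seq(7, 70, 7), phases_min = 8,
                       phases_max = 8, noise_cv = 0.05, animal_cv = 0,
                       body_weight_sd = 0)
  co <- simulate_cohort(cfg, seed = 21)
  an <- analyze_cohort(co, quiet = TRUE)
  d <- an$daily
  for (l in LIMB_LABELS) for (p in c("grf_peak_pct", "grf_mean_pct", "t_c")) {
    tru_col <- if (p == "t_c") "t_c" else p
    got <- d[d$limb == l & d$parameter == p, ]
    got <- got[order(got$day_postop), ]
    tru <- co$truth[co$truth$limb == l, ]
    tru <- tru[order(tru$day_postop), tru_col]
    rel <- abs(got$mean - tru) / tru
    expect_lt(mean(rel), 0.03)
  }
})
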