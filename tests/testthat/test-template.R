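test_that("half-sine template has the closed-form mean/peak ratio and exact peak", {
  f <- stance_template(template_params(42, 0.58), 1000)
  n <- length(f)
  expect_equal(max(f), 42)
  mean_f <- (sum(f) - (f[1] + f[n]) / 2) / (n - 1)
  expect_equal(mean_f / max(f), 2 / pi, tolerance = 1e-5)
  expect_equal(f[1], 0, tolerance = 1e-12)
  expect_equal(f[n], 0, tolerance = 1e-12)
})

test_that("the sampled maximum equals the requested peak for any shape", {
  set.seed(7)
  for (i in 1:25) {
    tp <- template_params(peak_frac = runif(1, 5, 80),
                          t_c = runif(1, 0.2, 1.0),
                          dip_depth = runif(1, 0, 0.95),
                          hump_asymmetry = runif(1, 0.5, 1.5),
                          sharpness = runif(1, 1, 2.5))
    f <- stance_template(tp, 50)
    expect_identical(max(f), tp$peak_frac)
    expect_lt(f[1], 1e-9)
    expect_lt(f[length(f)], 1e-9)
  }
})

test_that("a deep valley produces two maxima and one interior minimum", {
  f <- stance_template(template_params(42, 0.58, dip_depth = 0.5), 200)
  d1 <- diff(f)
  turns <- diff(sign(d1))
  expect_equal(sum(turns < 0), 2)   # local maxima
  expect_equal(sum(turns > 0), 1)   # local minimum, strictly interior
  # and a shallow valley keeps a single hump
  f0 <- stance_template(template_params(42, 0.58, dip_depth = 0.2), 200)
  expect_equal(sum(diff(sign(diff(f0))) < 0), 1)
})

test_that("contact times shorter than 8 samples raise a resolution error", {
  expect_error(stance_template(template_params(42, 0.10), 50),
               class = "gaitrec_resolution")
  expect_silent(stance_template(template_params(42, 0.16), 50))
})

test_that("invalid shape parameters are rejected", {
  expect_error(template_params(42, 0.58, dip_depth = 1), class = "gaitrec_validation")
  expect_error(template_params(42, 0.58, dip_depth = -0.1), class = "gaitrec_validation")
  expect_error(template_params(-1, 0.58), class = "gaitrec_validation")
  expect_error(template_params(42, 0), class = "gaitrec_validation")
})

test_that("dip-depth calibration solves the target ratio on both branches", {
  # half-sine target lands on d = 0
  expect_equal(solve_dip_depth(2 / pi), 0, tolerance = 1e-4)
  # control hind ratio, deep branch: verified by re-simulating the template
  d <- solve_dip_depth(28 / 42, branch = "deep")
  f <- stance_template(template_params(42, 0.58, dip_depth = d), 2000)
  n <- length(f)
  mean_f <- (sum(f) - (f[1] + f[n]) / 2) / (n - 1)
  expect_equal(mean_f / max(f), 28 / 42, tolerance = 1e-4)
  # flat branch can hit the same ratio with a shallow single hump
  d_flat <- solve_dip_depth(28 / 42, branch = "flat")
  expect_lt(d_flat, 0.5)
  f2 <- stance_template(template_params(42, 0.58, dip_depth = d_flat), 2000)
  mean2 <- (sum(f2) - (f2[1] + f2[length(f2)]) / 2) / (length(f2) - 1)
  expect_equal(mean2 / max(f2), 28 / 42, tolerance = 1e-4)
})

test_that("unachievable mean/peak ratios raise a domain error naming the interval", {
  err <- expect_error(solve_dip_depth(0.99), class = "gaitrec_domain")
  expect_match(conditionMessage(err), "achievable")
  expect_error(solve_dip_depth(0.99, branch = "deep"), class = "gaitrec_domain")
  expect_error(solve_dip_depth(0.30, branch = "deep"), class = "gaitrec_domain")
})

test_that("the mean/peak ratio is strictly decreasing in dip depth on the deep branch", {
  ds <- seq(0.55, 0.99, by = 0.02)
  rs <- vapply(ds, gaitrec:::template_mean_peak_ratio, numeric(1))
  expect_true(all(diff(rs) < 0))
})
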