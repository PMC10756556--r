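test_that("a perfect line is fitted exactly and labelled very strong", {
  x <- 1:10
  ft <- ols_fit(x, 2 * x + 1)
  expect_equal(ft$slope, 2)
  expect_equal(ft$intercept, 1)
  expect_equal(ft$r_squared, 1)
  expect_equal(ft$strength, "very strong")
  expect_true(ft$significant)
  expect_equal(unname(coef(ft)), c(1, 2))
})

test_that("a constant response is the legal null fit; a constant predictor errors", {
  ft <- ols_fit(1:8, rep(3.5, 8))
  expect_equal(ft$slope, 0)
  expect_equal(ft$r_squared, 0)
  expect_equal(ft$p_value, 1)
  expect_equal(ft$strength, "none")
  expect_error(ols_fit(rep(2, 5), 1:5), class = "gaitrec_degenerate")
  expect_error(ols_fit(1:2, 1:2), class = "gaitrec_insufficient")
})

test_that("slope, R-squared and p-value match the normal-equations + t-CDF oracle", {
  set.seed(101)
  for (i in 1:5) {
    x <- runif(20, 0, 100)
    y <- 0.1 * x + rnorm(20, sd = 4)
    ft <- ols_fit(x, y)
    or <- ols_oracle(x, y)
    expect_equal(ft$slope, or$slope, tolerance = 1e-10)
    expect_equal(ft$intercept, or$intercept, tolerance = 1e-10)
    expect_equal(ft$r_squared, or$r_squared, tolerance = 1e-10)
    expect_equal(ft$p_value, or$p_value, tolerance = 1e-10)
    # R^2 equals the squared sample correlation
    expect_equal(ft$r_squared, stats::cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("the t-test p-value agrees with a permutation p-value within Monte-Carlo error", {
  set.seed(202)
  x <- runif(15, 0, 10)
  y <- 0.35 * x + rnorm(15, sd = 2.2)
  ft <- ols_fit(x, y)
  n_perm <- 2000
  obs <- abs(ols_oracle(x, y)$slope)
  exceed <- replicate(n_perm, abs(ols_oracle(x, sample(y))$slope) >= obs)
  p_perm <- (sum(exceed) + 1) / (n_perm + 1)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(ft$p_value - p_perm), max(4 * mc_sd, 0.02))
})

test_that("collinear no-noise trajectories give an all-ones R-squared matrix", {
  # one operated animal, no noise, force trajectories all linear pre-recovery
  cfg <- cohort_config(n_operated = 1, n_control = 0,
                       session_days = seq(14, 154, 28), phases_min = 3,
                       phases_max = 3, noise_cv = 0, animal_cv = 0,
                       body_weight_sd = 0)
  co <- simulate_cohort(cfg, seed = 8)
  an <- analyze_cohort(co, quiet = TRUE)
  cm <- correlation_matrix(an$daily, parameters = "grf_peak_pct",
                           limbs = c("IH", "CH", "IF", "CF"))
  expect_true(all(cm$r_squared > 1 - 1e-9))
  expect_equal(unname(diag(cm$r_squared)), rep(1, nrow(cm$r_squared)))
  expect_equal(cm$r_squared, t(cm$r_squared))
})

test_that("force parameters of a limb correlate more tightly than contact times across limbs", {
  cfg <- cohort_config(n_operated = 2, n_control = 0,
                       session_days = seq(7, 154, 14), phases_min = 6,
                       phases_max = 6, noise_cv = 0.05)
  co <- simulate_cohort(cfg, seed = 12)
  an <- analyze_cohort(co, quiet = TRUE)
  cm <- correlation_matrix(an$daily,
                           parameters = c("grf_peak_pct", "grf_mean_pct", "t_c"))
  expect_gt(cm$r_squared["IH.grf_peak_pct", "IH.grf_mean_pct"],
            cm$r_squared["IH.t_c", "CF.t_c"])
})

test_that("cells with too few pairs are flagged missing", {
  d <- rbind(make_daily(limb = "IH", day = c(7, 14), parameter = "grf_peak_pct",
                        mean = c(23, 25)),
             make_daily(limb = "CH", day = c(7, 14), parameter = "grf_peak_pct",
                        mean = c(50, 48)))
  cm <- correlation_matrix(d, parameters = "grf_peak_pct",
                           limbs = c("IH", "CH"), include_time = FALSE)
  expect_true(is.na(cm$r_squared["IH.grf_peak_pct", "CH.grf_peak_pct"]))
  expect_equal(cm$n["IH.grf_peak_pct", "CH.grf_peak_pct"], 2L)
})
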