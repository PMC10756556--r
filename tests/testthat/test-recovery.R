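test_that("recovery day is the first persistent entry into the control band", {
  days <- seq(7, 210, 7)
  # already at control: first day of the series
  expect_equal(recovery_time(days, rep(42, length(days)), 42), 7)
  # noise-free linear rise 23 -> 42 over days 7 -> 160: the 5% band edge
  # 0.95 * 42 = 39.9 is crossed at day 7 + 153 * (39.9 - 23) / 19 = 143.1,
  # so the first weekly session inside the band is day 147
  v <- 23 + (42 - 23) * pmin(1, (days - 7) / 153)
  expect_equal(recovery_time(days, v, 42, 0.05), 147)
  # a series that dips back out of the band counts the later, persistent entry
  v2 <- v
  v2[days == 161] <- 39.0
  expect_equal(recovery_time(days, v2, 42, 0.05), 168)
  # never recovered
  expect_true(is.na(recovery_time(days, rep(20, length(days)), 42)))
  expect_error(recovery_time(numeric(0), numeric(0), 42),
               class = "gaitrec_insufficient")
})

test_that("shrinking the tolerance can only delay the recovery day", {
  set.seed(40)
  days <- seq(7, 210, 7)
  for (i in 1:20) {
    v <- 23 + (42 - 23) * pmin(1, (days - 7) / 153) + rnorm(length(days), sd = 0.6)
    tols <- c(0.10, 0.05, 0.02)
    rd <- vapply(tols, function(tf) {
      r <- recovery_time(days, v, 42, tf)
      if (is.na(r)) 9999 else r
    }, numeric(1))
    expect_true(all(diff(rd) >= 0))
  }
})

test_that("the recovery rate converts the OLS slope to %BW per month", {
  days <- seq(0, 160, 8)
  flat <- recovery_rate(days, rep(30, length(days)))
  expect_equal(flat$rate_per_month, 0)
  # exact line gaining 19 %BW over 160 days: 19/160 * 30.44 = 3.61
  line <- 23 + 19 * days / 160
  rr <- recovery_rate(days, line)
  expect_equal(rr$rate_per_month, 19 / 160 * 30.44, tolerance = 1e-10)
  expect_equal(round(rr$rate_per_month, 2), 3.61)
  # OLS slope is invariant to downsampling an exact line
  keep <- seq(1, length(days), 2)
  rr2 <- recovery_rate(days[keep], line[keep])
  expect_equal(rr2$rate_per_month, rr$rate_per_month, tolerance = 1e-10)
  # window restriction and insufficient data
  rr3 <- recovery_rate(days, line, window = c(40, 120))
  expect_equal(rr3$rate_per_month, rr$rate_per_month, tolerance = 1e-10)
  expect_error(recovery_rate(c(1, 2), c(1, 2)), class = "gaitrec_insufficient")
})

test_that("fit_recovery pools animals and exposes the model through its methods", {
  days <- seq(7, 210, 7)
  d <- do.call(rbind, lapply(c("OP01", "OP02"), function(a) {
    v <- 23 + (42 - 23) * pmin(1, (days - 7) / 153)
    make_daily(animal = a, limb = "IH", day = days,
               parameter = "grf_peak_pct", mean = v)
  }))
  fr <- fit_recovery(d, "IH", "grf_peak_pct")
  expect_s3_class(fr, "gait_recovery")
  expect_equal(fr$recovery_day, 147)
  expect_equal(fr$rate_per_month, 19 / 153 * 30.44, tolerance = 1e-6)
  expect_equal(fr$control_ref, 42)
  expect_equal(unname(coef(fr)["slope"]), 19 / 153, tolerance = 1e-6)
  expect_equal(predict(fr, 160), fr$fit$intercept + fr$fit$slope * 160)
  expect_output(print(fr), "recovery day 147")
  expect_output(summary(fr), "R-squared")
  # animals filter drops the flat control animal from the pooled series
  ctrl <- make_daily(animal = "CT01", limb = "IH", day = days,
                     parameter = "grf_peak_pct", mean = rep(42, length(days)))
  fr2 <- fit_recovery(rbind(d, ctrl), "IH", "grf_peak_pct",
                      animals = c("OP01", "OP02"))
  expect_equal(fr2$rate_per_month, fr$rate_per_month)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fr))
})
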