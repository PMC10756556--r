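# shared fixture builders; everything is generated in code at test time

# a recording of n_phases noise-free template bumps separated by fixed gaps,
# with the ground-truth onset/offset sample of each bump attached
template_recording <- function(tp, n_phases = 3, gap_s = 0.5, fs = 50,
                               bw = 57.9, limb = "IH", day = 0) {
  npg <- round(gap_s * fs)
  pct <- stance_template(tp, fs)
  force <- numeric(0)
  onsets <- integer(n_phases)
  for (k in seq_len(n_phases)) {
    force <- c(force, numeric(npg))
    onsets[k] <- length(force) + 1L
    force <- c(force, pct * bw * 9.81 / 100)
  }
  force <- c(force, numeric(npg))
  rec <- force_recording(force, fs, "A1", limb, day, bw)
  attr(rec, "onsets") <- onsets
  attr(rec, "offsets") <- onsets + length(pct) - 1L
  rec
}

# tiny daily-summary frame in the long format of aggregate_daily()
make_daily <- function(animal = "A1", limb, day, parameter, mean, sd = 0, n = 8) {
  out <- data.frame(animal_id = animal, limb = limb, day_postop = day,
                    parameter = parameter, mean = mean, sd = sd, n_phases = n)
  class(out) <- c("daily_summary", "data.frame")
  out
}

# independent OLS oracle: normal equations + t CDF, no lm()
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  se <- sqrt(ss_res / (n - 2) / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept, r_squared = r2,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}
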