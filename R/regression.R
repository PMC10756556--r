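#' Ordinary least-squares fit with goodness-of-fit labels
#'
#' Simple linear regression of `y` on `x` via [stats::lm()], reporting slope,
#' intercept, R-squared, and the two-sided p-value of the slope from the t
#' statistic with n - 2 degrees of freedom. Following force-platform practice,
#' R-squared >= 0.49 is labelled a strong and >= 0.81 a very strong
#' correlation; significance is conventionally declared at p < 0.01. A
#' constant response is a legal degenerate case with slope 0, R-squared 0 (the
#' residual and total sums of squares coincide) and p = 1; a constant
#' predictor is an error.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return An object of class `ols_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, `strength` (`"none"`, `"strong"`,
#'   `"very strong"`) and `significant` (p < 0.01).
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y))
    stop_gaitrec("x and y must have equal length", "gaitrec_validation")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop_gaitrec("need at least 3 points for a regression", "gaitrec_insufficient")
  if (stats::var(x) == 0)
    stop_gaitrec("constant predictor: degenerate design", "gaitrec_degenerate")
  if (stats::var(y) == 0) {
    fit <- list(slope = 0, intercept = y[1], r_squared = 0, p_value = 1,
                n = length(x))
  } else {
    m <- stats::lm(y ~ x)
    # summary.lm warns on numerically perfect fits; those are legal here
    sm <- suppressWarnings(summary(m))
    fit <- list(slope = unname(stats::coef(m)[2]),
                intercept = unname(stats::coef(m)[1]),
                r_squared = sm$r.squared,
                p_value = unname(sm$coefficients[2, 4]),
                n = length(x))
  }
  fit$strength <- if (fit$r_squared >= 0.81) "very strong"
    else if (fit$r_squared >= 0.49) "strong" else "none"
  fit$significant <- fit$p_value < 0.01
  class(fit) <- "ols_fit"
  fit
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> slope %.4g, intercept %.4g, R^2 %.3f (%s), p %.3g%s, n %d\n",
              x$slope, x$intercept, x$r_squared, x$strength, x$p_value,
              if (x$significant) " *" else "", x$n))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Limb-by-parameter R-squared matrix
#'
#' Builds the grid of pairwise simple-regression R-squared values between all
#' (limb, parameter) daily-mean series, with day post-surgery included as an
#' additional pseudo-variable ("time"). Observations are the per-animal daily
#' means, matched by (animal, day) and pooled across animals (each animal-day
#' is a replicate); a per-animal sensitivity mode averages animals per day
#' first. Cells with fewer than 3 complete pairs are flagged missing. The
#' matrix is symmetric with unit diagonal since the R-squared of a simple
#' regression does not depend on which variable is the response.
#'
#' @param summaries A `daily_summary` frame (typically operated animals only).
#' @param parameters Parameter names to include (default all five).
#' @param limbs Limb labels to include (default all four).
#' @param include_time Include day post-surgery as a variable (default TRUE).
#' @param pooling `"pooled"` (default) or `"per_animal"`.
#' @param alpha Significance threshold on the slope p-value (default 0.01).
#' @param bonferroni Apply a Bonferroni correction across the upper triangle
#'   before flagging significance (default FALSE, matching the raw-p
#'   convention of force-platform studies).
#' @return An object of class `correlation_matrix`: list with `r_squared` and
#'   `significant` matrices, `n` (pairs per cell) and the settings.
#' @export
correlation_matrix <- function(summaries, parameters = GAIT_PARAMETERS,
                               limbs = LIMB_LABELS, include_time = TRUE,
                               pooling = c("pooled", "per_animal"),
                               alpha = 0.01, bonferroni = FALSE) {
  pooling <- match.arg(pooling)
  s <- summaries[summaries$parameter %in% parameters & summaries$limb %in% limbs, ]
  if (pooling == "per_animal") {
    agg <- stats::aggregate(mean ~ limb + day_postop + parameter, data = s, FUN = mean)
    agg$animal_id <- "pooled"
    s <- agg
  }
  # wide: one row per (animal, day), one column per limb.parameter
  s$var <- paste(s$limb, s$parameter, sep = ".")
  s$obs <- paste(s$animal_id, s$day_postop, sep = "@")
  vars <- unique(s$var)
  obs <- unique(s$obs)
  w <- matrix(NA_real_, length(obs), length(vars),
              dimnames = list(obs, vars))
  w[cbind(match(s$obs, obs), match(s$var, vars))] <- s$mean
  if (include_time) {
    day <- as.numeric(sub(".*@", "", obs))
    w <- cbind(w, time = day)
    vars <- c(vars, "time")
  }
  k <- length(vars)
  r2 <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  pv <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  np <- matrix(0L, k, k, dimnames = list(vars, vars))
  diag(r2) <- 1
  diag(pv) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- is.finite(w[, i]) & is.finite(w[, j])
    np[i, j] <- np[j, i] <- sum(ok)
    if (sum(ok) < 3L) next
    ft <- tryCatch(ols_fit(w[ok, i], w[ok, j]),
                   gaitrec_degenerate = function(e) NULL)
    if (is.null(ft)) next
    r2[i, j] <- r2[j, i] <- ft$r_squared
    pv[i, j] <- pv[j, i] <- ft$p_value
  }
  thr <- if (bonferroni) alpha / (k * (k - 1) / 2) else alpha
  structure(list(r_squared = r2, significant = pv < thr, p_value = pv,
                 n = np, alpha = alpha, bonferroni = bonferroni,
                 pooling = pooling),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  m <- format(round(x$r_squared, digits))
  m[x$significant %in% TRUE] <- paste0(m[x$significant %in% TRUE], "*")
  m[is.na(x$r_squared)] <- "."
  cat(sprintf("<correlation_matrix> R-squared (%s pooling; * = p < %g%s)\n",
              x$pooling, x$alpha,
              if (x$bonferroni) ", Bonferroni" else ""))
  print(m, quote = FALSE)
  invisible(x)
}
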