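#' Paired method-comparison series
#'
#' @param test_values Per-subject measurements of the method under test.
#' @param reference_values Per-subject gold-standard measurements.
#' @param labels Subject identifiers.
#' @return An object of class `paired_series`.
#' @export
paired_series <- function(test_values, reference_values,
                          labels = seq_along(test_values)) {
  if (length(test_values) != length(reference_values))
    pwv_abort("pairing_error", "test and reference series differ in length")
  if (length(test_values) < 3L)
    pwv_abort("sample_size_error", "need >= 3 paired measurements")
  if (!all(is.finite(test_values)) || !all(is.finite(reference_values)))
    pwv_abort("pairing_error", "non-finite values in a paired series")
  structure(list(test_values = as.numeric(test_values),
                 reference_values = as.numeric(reference_values),
                 labels = labels),
            class = "paired_series")
}

#' Paired method-agreement statistics
#'
#' The full paired-comparison battery for a method against a reference
#' standard: Pearson correlation with its two-sided t-test p-value,
#' coefficient of variation (SD of the paired differences divided by the
#' mean of all measurements of both series, in %), mean unsigned error
#' (mean of per-subject |difference|/reference, in %, with its SD), mean and
#' SD of the differences with the paired two-sided t-test, the t-based 95%
#' confidence interval of the mean difference, and Bland-Altman limits of
#' agreement (mean +/- 1.96 SD of the differences).
#'
#' All statistics are computed in closed form so that the degenerate case
#' sd_diff = 0 (identical series) yields a defined report (p_ttest = NA,
#' degenerate interval) instead of an error.
#'
#' @param series A `paired_series` (n >= 3; both series must vary).
#' @param mue_units `"percent"` (per-subject |d|/reference * 100, default)
#'   or `"absolute"` (|d| in measurement units).
#' @return An object of class `agreement_report`.
#' @export
agreement <- function(series, mue_units = c("percent", "absolute")) {
  stopifnot(inherits(series, "paired_series"))
  mue_units <- match.arg(mue_units)
  x <- series$test_values
  y <- series$reference_values
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    pwv_abort("degenerate_statistics_error",
              "zero variance in a series: correlation undefined")
  r <- stats::cor(x, y)
  p_r <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  d <- x - y
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  cov_pct <- 100 * sd_diff / mean(c(x, y))
  ue <- if (mue_units == "percent") 100 * abs(d) / y else abs(d)
  mue <- mean(ue)
  mue_sd <- stats::sd(ue)
  if (sd_diff > 0) {
    tstat <- mean_diff / (sd_diff / sqrt(n))
    p_t <- 2 * stats::pt(-abs(tstat), df = n - 1)
  } else {
    p_t <- NA_real_
  }
  ci <- ci95_from_summary(mean_diff, sd_diff, n)
  structure(list(pearson_r = r, p_r = p_r, cov_pct = cov_pct,
                 mue_pct = mue, mue_sd_pct = mue_sd, mue_units = mue_units,
                 mean_diff = mean_diff, sd_diff = sd_diff,
                 ci95_lo = ci[1L], ci95_hi = ci[2L], p_ttest = p_t,
                 loa_lo = mean_diff - 1.96 * sd_diff,
                 loa_hi = mean_diff + 1.96 * sd_diff, n = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report> n=%d\n",
                     "  r = %.3f (p = %.3g), COV = %.1f%%\n",
                     "  mean unsigned error = %.1f +/- %.1f %s\n",
                     "  mean diff = %.3f +/- %.3f (p = %.3g), 95%%-CI (%.3f, %.3f)\n",
                     "  limits of agreement (%.3f, %.3f)\n"),
              x$n, x$pearson_r, x$p_r, x$cov_pct, x$mue_pct, x$mue_sd_pct,
              if (x$mue_units == "percent") "%" else "units",
              x$mean_diff, x$sd_diff, x$p_ttest, x$ci95_lo, x$ci95_hi,
              x$loa_lo, x$loa_hi))
  invisible(x)
}

#' t-based 95% CI of a mean difference from its summary statistics
#'
#' mean_diff +/- t(0.975, n-1) * sd_diff / sqrt(n).
#'
#' @param mean_diff Mean of the paired differences.
#' @param sd_diff SD of the paired differences (>= 0).
#' @param n Number of pairs (>= 2).
#' @return Numeric `c(lo, hi)`.
#' @export
ci95_from_summary <- function(mean_diff, sd_diff, n) {
  if (n < 2L) pwv_abort("sample_size_error", "need n >= 2 for a CI")
  if (sd_diff < 0) pwv_abort("domain_error", "sd_diff must be >= 0")
  half <- stats::qt(0.975, df = n - 1) * sd_diff / sqrt(n)
  c(mean_diff - half, mean_diff + half)
}

#' Compare two methods' association with a shared reference
#'
#' Tests whether two methods relate differently to the same gold standard,
#' by linear regression of the stacked measurements on the reference value,
#' a method indicator, and their interaction; the returned p-value is the
#' two-sided test of the interaction coefficient (a slope contrast).
#'
#' @param series_a,series_b `paired_series` sharing the same reference
#'   subjects (identical reference values, in order).
#' @return List with `p_interaction`, the fitted `coefficients`, and the
#'   `lm` fit.
#' @export
compare_method_correlations <- function(series_a, series_b) {
  stopifnot(inherits(series_a, "paired_series"),
            inherits(series_b, "paired_series"))
  if (length(series_a$reference_values) != length(series_b$reference_values) ||
      max(abs(series_a$reference_values - series_b$reference_values)) > 1e-9)
    pwv_abort("pairing_error", "series do not share the same reference subjects")
  n <- length(series_a$test_values)
  dat <- data.frame(
    y = c(series_a$test_values, series_b$test_values),
    ref = rep(series_a$reference_values, 2L),
    method = rep(c(0, 1), each = n))
  fit <- stats::lm(y ~ ref + method + ref:method, data = dat)
  ct <- summary(fit)$coefficients
  p <- if ("ref:method" %in% rownames(ct)) ct["ref:method", 4L] else NA_real_
  list(p_interaction = unname(p), coefficients = stats::coef(fit), fit = fit)
}

#' Steiger's z-test for two dependent correlations sharing one variable
#'
#' Labeled alternative to the interaction-regression contrast: compares
#' r(a, ref) with r(b, ref) accounting for r(a, b). Not the default
#' correlation contrast.
#'
#' @param series_a,series_b `paired_series` sharing the same reference.
#' @return List with `z` and two-sided `p`.
#' @export
steiger_dependent_cor_test <- function(series_a, series_b) {
  if (max(abs(series_a$reference_values - series_b$reference_values)) > 1e-9)
    pwv_abort("pairing_error", "series do not share the same reference subjects")
  n <- length(series_a$test_values)
  r1 <- stats::cor(series_a$test_values, series_a$reference_values)
  r2 <- stats::cor(series_b$test_values, series_b$reference_values)
  r12 <- stats::cor(series_a$test_values, series_b$test_values)
  z1 <- atanh(r1); z2 <- atanh(r2)
  rbar2 <- ((r1 + r2) / 2)^2
  cov_num <- r12 * (1 - 2 * rbar2) - 0.5 * rbar2 * (1 - 2 * rbar2 - r12^2)
  s <- cov_num / ((1 - rbar2)^2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
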