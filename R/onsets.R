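#' Systolic wave-front onset estimate
#'
#' The foot time of the systolic wave front on one cardiac cycle, with the
#' diagnostics of the fit that produced it.
#'
#' @param onset_s Foot time, seconds relative to the R-wave (real-valued,
#'   not snapped to the sampling grid).
#' @param baseline_level Diastolic baseline level, signal units.
#' @param upslope_slope Fitted upslope slope, signal units per second.
#' @param upslope_intercept Fitted upslope intercept, signal units.
#' @param n_fit_samples Number of points entering the upslope fit.
#' @param valid Logical validity flag.
#' @param reason Reason code, `"ok"` when nothing noteworthy happened.
#' @return An object of class `onset_estimate`.
#' @export
onset_estimate <- function(onset_s, baseline_level = NA_real_,
                           upslope_slope = NA_real_,
                           upslope_intercept = NA_real_,
                           n_fit_samples = NA_integer_,
                           valid = TRUE, reason = "ok") {
  structure(list(onset_s = onset_s, baseline_level = baseline_level,
                 upslope_slope = upslope_slope,
                 upslope_intercept = upslope_intercept,
                 n_fit_samples = n_fit_samples,
                 valid = isTRUE(valid), reason = reason),
            class = "onset_estimate")
}

#' @export
print.onset_estimate <- function(x, ...) {
  cat(sprintf("<onset_estimate> onset=%.5fs baseline=%.4g slope=%.4g n_fit=%s %s (%s)\n",
              x$onset_s, x$baseline_level, x$upslope_slope,
              as.character(x$n_fit_samples),
              if (x$valid) "valid" else "INVALID", x$reason))
  invisible(x)
}

# linear interpolation of the time at which the segment (t1,v1)-(t2,v2)
# crosses `level`
.interp_cross <- function(t1, t2, v1, v2, level) {
  if (v2 == v1) return(t1)
  t1 + (level - v1) / (v2 - v1) * (t2 - t1)
}

#' Detect the systolic onset on a velocity cycle
#'
#' Implements the onset-intersection algorithm: the foot is the intersection
#' of (i) a horizontal line modelling the constant diastolic flow and (ii) a
#' straight line fitted by least squares to the systolic upslope samples
#' whose values lie within 20% and 80% of the total range between the
#' pre-systolic trough and the systolic peak. The interpolated first-crossing
#' points of the two thresholds are included as fit points, which keeps the
#' fit determined at coarse (e.g. 35 phases/cycle) sampling.
#'
#' The trough is the cycle minimum interpreted cyclically as preceding the
#' peak. The rising limb starts at the pre-systolic trough, operationalized
#' as the last point at trough level (within 5% of the range) before the
#' peak, and runs from there to the peak; anchoring the limb this way keeps
#' a noisy global minimum elsewhere in diastole from pulling the limb (and
#' the baseline window) through the decay. The baseline level is the median
#' of the samples in the cyclic window covering the final 20% of the R-R
#' interval before the pre-systolic trough (the diastolic plateau). Ties for
#' peak/trough resolve to the earliest sample.
#'
#' @param cycle Velocity `sampled_waveform` (one cycle, time 0 = R-wave).
#' @param noise_floor_frac Minimum peak-trough range, as a fraction of the
#'   waveform's absolute maximum, below which the cycle is declared flat.
#' @param min_fit_samples Minimum number of fit points (>= 3).
#' @return An `onset_estimate`.
#' @export
detect_onset_velocity <- function(cycle, noise_floor_frac = 0.05,
                                  min_fit_samples = 3L) {
  stopifnot(inherits(cycle, "sampled_waveform"))
  v <- cycle$values
  t <- wf_times(cycle)
  n <- length(v)
  rr <- cycle$rr_s
  pk <- which.max(v)
  tr <- which.min(v)
  rng <- v[pk] - v[tr]
  vmax <- max(abs(v))
  if (rng <= 0 || vmax == 0 || rng < noise_floor_frac * vmax)
    pwv_abort("no_upslope_error",
              "flat curve: peak-trough range below the noise floor")
  # cyclic sample order ending at the peak (samples after the peak are the
  # tail of the previous cycle)
  if (pk == n) {
    ord <- 1:n
    t_ord <- t
  } else {
    ord <- c((pk + 1L):n, 1:pk)
    t_ord <- c(t[(pk + 1L):n] - rr, t[1:pk])
  }
  v_ord <- v[ord]
  # pre-systolic trough = last point at trough level before the peak; the
  # rising limb runs from there to the peak (a global minimum elsewhere in
  # diastole would otherwise pull the limb through the decay)
  m <- length(ord)
  cand <- which(v_ord[-m] <= v[tr] + 0.05 * rng)
  r0 <- if (length(cand)) cand[length(cand)] else 1L
  tl <- t_ord[r0:m]
  vl <- v_ord[r0:m]
  lo <- v[tr] + 0.2 * rng
  hi <- v[tr] + 0.8 * rng
  # diastolic baseline: median over the cyclic window covering the final 20%
  # of the RR interval preceding the trough
  t_trough <- tl[1L]
  dt_back <- (t_trough - t) %% rr
  w <- dt_back > 0 & dt_back <= 0.2 * rr
  if (!any(w)) w <- rep(TRUE, n)
  baseline <- stats::median(v[w])
  # Interpolated first up-crossings of the thresholds. A crossing is used
  # only when its bracketing segment lies wholly on the systolic upslope:
  # the lower anchor must sit clearly above the diastolic plateau (a segment
  # rising straight off the plateau starts before the foot), and the upper
  # anchor must not be the limb's peak sample (such a segment may straddle
  # the true peak). Either violation would bias the interpolated time.
  anchor_level <- baseline + 0.05 * rng
  cross_at <- function(thresh, strict = TRUE) {
    j <- which(vl >= thresh)[1L]
    if (is.na(j) || j == 1L) return(NULL)
    if (strict && (j == length(vl) || vl[j - 1L] <= anchor_level))
      return(NULL)
    c(.interp_cross(tl[j - 1L], tl[j], vl[j - 1L], vl[j], thresh), thresh)
  }
  c_lo <- cross_at(lo)
  c_hi <- cross_at(hi)
  inb <- vl >= lo & vl <= hi
  # with too few clean points, fall back to the unrestricted crossings: a
  # mildly biased foot is preferable to an undetectable one
  if (sum(inb) + length(c_lo) / 2 + length(c_hi) / 2 < min_fit_samples) {
    if (is.null(c_lo)) c_lo <- cross_at(lo, strict = FALSE)
    if (is.null(c_hi)) c_hi <- cross_at(hi, strict = FALSE)
  }
  tf <- c(c_lo[1L], tl[inb], c_hi[1L])
  vf <- c(c_lo[2L], vl[inb], c_hi[2L])
  keep <- !duplicated(signif(tf, 12))
  tf <- tf[keep]
  vf <- vf[keep]
  if (length(tf) < min_fit_samples)
    pwv_abort("insufficient_samples_error",
              sprintf("only %d samples in the 20-80%% upslope band",
                      length(tf)))
  mx <- mean(tf)
  my <- mean(vf)
  sxx <- sum((tf - mx)^2)
  if (sxx <= 0)
    pwv_abort("insufficient_samples_error", "degenerate upslope time support")
  slope <- sum((tf - mx) * (vf - my)) / sxx
  intercept <- my - slope * mx
  if (slope <= 0)
    pwv_abort("non_physical_slope_error", "non-positive fitted upslope slope")
  onset <- (baseline - intercept) / slope
  valid <- is.finite(onset) && onset >= t_trough - 0.02 * rr &&
    onset <= tl[length(tl)] + 0.02 * rr
  onset_estimate(onset_s = onset, baseline_level = baseline,
                 upslope_slope = slope, upslope_intercept = intercept,
                 n_fit_samples = length(tf), valid = valid,
                 reason = if (valid) "ok" else "onset_outside_cycle")
}

#' Detect the systolic onset on a pressure cycle
#'
#' The foot is the time (relative to the R-wave) of the minimal pressure
#' prior to the upslope of the systolic pressure wave: the minimum sample on
#' the interval from the cycle start to the systolic peak. Ties resolve to
#' the earliest sample. A minimum attained at the very first sample (a
#' monotone-increasing cycle) is returned valid with reason
#' `"min_at_cycle_start"`.
#'
#' @param cycle Pressure `sampled_waveform` (one cycle, time 0 = R-wave).
#' @return An `onset_estimate` (slope diagnostics are `NA`: no line is fit).
#' @export
detect_onset_pressure <- function(cycle) {
  stopifnot(inherits(cycle, "sampled_waveform"))
  v <- cycle$values
  t <- wf_times(cycle)
  pk <- which.max(v)
  if (pk == 1L)
    pwv_abort("no_upslope_error",
              "monotone-decreasing cycle: no systolic peak after a minimum")
  mi <- which.min(v[1:pk])
  onset_estimate(onset_s = t[mi], baseline_level = v[mi],
                 n_fit_samples = pk,
                 valid = TRUE,
                 reason = if (mi == 1L) "min_at_cycle_start" else "ok")
}

#' Aggregate per-cycle onsets into one site onset
#'
#' Pressure recordings cover many cardiac cycles to average out respiratory
#' variation; the per-cycle foot times are combined by their median
#' (robust to an occasional mis-detected cycle). The mean is available via
#' `method = "mean"`.
#'
#' @param per_cycle List of `onset_estimate` (invalid ones are dropped).
#' @param method `"median"` (default) or `"mean"`.
#' @return An `onset_estimate`; `$n_cycles` records the number of valid
#'   cycles aggregated.
#' @export
aggregate_onsets <- function(per_cycle, method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot(is.list(per_cycle))
  valid <- Filter(function(e) inherits(e, "onset_estimate") && e$valid,
                  per_cycle)
  if (length(valid) == 0L)
    pwv_abort("aggregation_error", "no valid per-cycle onset estimates")
  onsets <- vapply(valid, function(e) e$onset_s, numeric(1))
  agg <- if (method == "median") stats::median(onsets) else mean(onsets)
  out <- onset_estimate(
    onset_s = agg,
    baseline_level = stats::median(vapply(valid, function(e) e$baseline_level,
                                          numeric(1))),
    n_fit_samples = length(valid),
    valid = TRUE, reason = "ok")
  out$n_cycles <- length(valid)
  out
}
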