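#' Site onset: an onset estimate at an arc-length position
#'
#' @param arc_position_m Cumulative centerline distance from the
#'   aortic-valve end, metres (>= 0).
#' @param onset An `onset_estimate`.
#' @return An object of class `site_onset`.
#' @export
site_onset <- function(arc_position_m, onset) {
  stopifnot(inherits(onset, "onset_estimate"))
  if (!is.finite(arc_position_m) || arc_position_m < 0)
    pwv_abort("geometry_error", "arc_position_m must be finite and >= 0")
  structure(list(arc_position_m = arc_position_m, onset = onset),
            class = "site_onset")
}

.pwv_estimate <- function(pwv, method, delta_x_m, delta_t_s, n_sites,
                          slope_se_s_per_m = NA_real_, fit_r2 = NA_real_,
                          n_excluded = 0L) {
  structure(list(pwv_m_per_s = pwv, method = method,
                 delta_x_m = delta_x_m, delta_t_s = delta_t_s,
                 n_sites = n_sites, slope_se_s_per_m = slope_se_s_per_m,
                 fit_r2 = fit_r2, n_excluded = n_excluded),
            class = "pwv_estimate")
}

#' @export
print.pwv_estimate <- function(x, ...) {
  cat(sprintf("<pwv_estimate> %.3f m/s (%s) dx=%.4gm dt=%.4gs n=%d r2=%.4g\n",
              x$pwv_m_per_s, x$method, x$delta_x_m, x$delta_t_s,
              x$n_sites, x$fit_r2))
  invisible(x)
}

#' Two-site foot-to-foot PWV
#'
#' PWV = delta_x / delta_t, with delta_x the aortic path length between the
#' two measurement sites and delta_t the transit time of the systolic wave
#' front (downstream onset minus upstream onset).
#'
#' @param onset_a,onset_b `site_onset` objects at distinct arc positions.
#' @return A `pwv_estimate` with `method = "two_site"`.
#' @export
two_site_pwv <- function(onset_a, onset_b) {
  stopifnot(inherits(onset_a, "site_onset"), inherits(onset_b, "site_onset"))
  if (!onset_a$onset$valid || !onset_b$onset$valid)
    pwv_abort("insufficient_sites_error", "both site onsets must be valid")
  dx <- onset_b$arc_position_m - onset_a$arc_position_m
  if (dx == 0)
    pwv_abort("geometry_error", "identical site positions")
  if (dx > 0) {
    dt <- onset_b$onset$onset_s - onset_a$onset$onset_s
  } else {
    dx <- -dx
    dt <- onset_a$onset$onset_s - onset_b$onset$onset_s
  }
  if (dt <= 0)
    pwv_abort("non_physical_propagation_error",
              "downstream onset does not lag the upstream onset")
  .pwv_estimate(dx / dt, "two_site", dx, dt, 2L, fit_r2 = 1)
}

# least squares of y on x with slope SE and R^2 (closed form)
.ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) pwv_abort("geometry_error", "degenerate site positions")
  b <- sum((x - mx) * (y - my)) / sxx
  a <- my - b * mx
  res <- y - (a + b * x)
  sse <- sum(res^2)
  ssy <- sum((y - my)^2)
  se_b <- if (n > 2) sqrt(sse / (n - 2) / sxx) else NA_real_
  r2 <- if (ssy > 0) 1 - sse / ssy else NA_real_
  list(alpha = a, beta = b, se_beta = se_b, r2 = r2)
}

#' Multi-site PWV by regression of onset time on arc position
#'
#' Ordinary least-squares fit onset_s = alpha + beta * arc_position_m over
#' the valid sites inside the window; PWV = 1/beta. This is the
#' velocity-propagation line fit along the centerline used for in-plane
#' velocity-encoded acquisitions with many sampling chords. Sites whose
#' onset detection failed are excluded and counted in `$n_excluded`.
#'
#' @param sites List of `site_onset`.
#' @param window Optional `c(s_min_m, s_max_m)` arc-length window; sites
#'   outside it are ignored.
#' @return A `pwv_estimate` with `method = "multi_site"`.
#' @export
multi_site_pwv <- function(sites, window = NULL) {
  stopifnot(is.list(sites))
  pos <- vapply(sites, function(s) s$arc_position_m, numeric(1))
  ok <- vapply(sites, function(s) isTRUE(s$onset$valid), logical(1))
  inw <- if (is.null(window)) rep(TRUE, length(sites)) else
    pos >= window[1] - 1e-12 & pos <= window[2] + 1e-12
  use <- ok & inw
  n_excl <- sum(inw & !ok)
  if (sum(use) < 2L)
    pwv_abort("insufficient_sites_error",
              sprintf("only %d valid sites in window", sum(use)))
  x <- pos[use]
  y <- vapply(sites[use], function(s) s$onset$onset_s, numeric(1))
  fit <- .ols(x, y)
  if (fit$beta <= 0)
    pwv_abort("non_physical_propagation_error",
              "non-positive propagation slope")
  dx <- max(x) - min(x)
  .pwv_estimate(1 / fit$beta, "multi_site", dx, fit$beta * dx,
                n_sites = sum(use), slope_se_s_per_m = fit$se_beta,
                fit_r2 = fit$r2, n_excluded = n_excl)
}

# one aggregated site onset from a multi-cycle recording
.recording_site_onset <- function(rec, detect = detect_onset_pressure,
                                  aggregate = "median") {
  cycles <- segment_cycles(rec)
  per <- lapply(cycles, function(cy) {
    tryCatch(detect(cy), aortapwv_error = function(e)
      onset_estimate(NA_real_, valid = FALSE, reason = conditionMessage(e)))
  })
  site_onset(rec$site_position_m, aggregate_onsets(per, method = aggregate))
}

#' PWV from a stepwise catheter pullback
#'
#' Pressure waveforms recorded at consecutive positions on a 5.8 cm grid
#' during catheter pullback. Per site, the recording is segmented at the
#' R-wave triggers, the pressure foot is detected on every cycle and the
#' per-cycle onsets are aggregated (median). Regional mode takes the
#' two-site PWV between the recordings nearest the two requested sites;
#' local mode regresses over all recordings within 5.8 cm of the requested
#' center (an 11.6 cm trajectory).
#'
#' @param recordings List of `multicycle_recording` with `site_position_m`.
#' @param mode `"regional"` or `"local"`.
#' @param site1_m,site2_m Regional mode: arc positions of the two sites.
#' @param center_m Local mode: arc position of the trajectory center.
#' @param max_snap_m Regional mode: maximum allowed distance between a
#'   requested site and the nearest recording (half a pullback step).
#' @param window_halfwidth_m Local mode: half-width of the trajectory.
#' @param detect Per-cycle onset detector (pressure by default).
#' @param aggregate Per-site aggregation rule, `"median"` or `"mean"`.
#' @return A `pwv_estimate` with `method = "pullback"`.
#' @export
pullback_pwv <- function(recordings, mode = c("regional", "local"),
                         site1_m = NULL, site2_m = NULL, center_m = NULL,
                         max_snap_m = 0.029, window_halfwidth_m = 0.058,
                         detect = detect_onset_pressure,
                         aggregate = "median") {
  mode <- match.arg(mode)
  stopifnot(is.list(recordings), length(recordings) >= 1L)
  pos <- vapply(recordings, function(r) r$site_position_m, numeric(1))
  if (mode == "regional") {
    stopifnot(!is.null(site1_m), !is.null(site2_m))
    i1 <- which.min(abs(pos - site1_m))
    i2 <- which.min(abs(pos - site2_m))
    if (abs(pos[i1] - site1_m) > max_snap_m ||
        abs(pos[i2] - site2_m) > max_snap_m)
      pwv_abort("site_match_error",
                "no pullback recording within half a step of a requested site")
    if (i1 == i2)
      pwv_abort("site_match_error", "both sites snap to the same recording")
    est <- two_site_pwv(.recording_site_onset(recordings[[i1]], detect, aggregate),
                        .recording_site_onset(recordings[[i2]], detect, aggregate))
  } else {
    stopifnot(!is.null(center_m))
    use <- which(abs(pos - center_m) <= window_halfwidth_m + 1e-9)
    if (length(use) < 2L)
      pwv_abort("insufficient_sites_error",
                "fewer than 2 pullback sites in the local window")
    sites <- lapply(recordings[use], .recording_site_onset,
                    detect = detect, aggregate = aggregate)
    est <- multi_site_pwv(sites)
  }
  est$method <- "pullback"
  est
}
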