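# Fixtures are built in code; all stochastic fixtures take an explicit seed.

# Analytic velocity cycle: plateau at `base` until t = foot, linear rise at
# `slope` (m/s)/s to `peak`, linear decay back to `base` by t = 0.5 s, then
# plateau to the end of the cycle. The 20-80% band lies on the rise line, so
# the detected onset is exactly `foot`.
piecewise_velocity_cycle <- function(fs = 2000, rr = 1.0, base = 0.05,
                                     foot = 0.10, slope = 8, peak = 0.9) {
  t <- seq(0, rr - 1 / fs, by = 1 / fs)
  t_pk <- foot + (peak - base) / slope
  v <- ifelse(t < foot, base,
       ifelse(t < t_pk, base + slope * (t - foot),
       ifelse(t < 0.5, peak - (peak - base) * (t - t_pk) / (0.5 - t_pk),
              base)))
  sampled_waveform(v, 1 / fs, 0, "velocity", rr)
}

# Pressure cycle with its pre-systolic minimum placed exactly at `foot`.
pressure_cycle <- function(fs = 2000, rr = 1.0, dbp = 76, pp = 50,
                           foot = 0.08) {
  t <- seq(0, rr - 1 / fs, by = 1 / fs)
  p <- dbp + pp * waveform_template(t / rr, onset_phase = foot / rr,
                                    kind = "pressure")
  sampled_waveform(p, 1 / fs, 0, "pressure", rr)
}

rect_contour <- function(w = 100, h = 20) {
  lumen_contour(c(0, w, w, 0), c(0, 0, h, h))
}

# Half annulus (half-ring) between radii r_in and r_out, centered at
# (cx, cy), opening downward in image coordinates (y grows down).
ring_contour <- function(r_in = 30, r_out = 50, cx = 50, cy = 60,
                         n_arc = 80) {
  th <- seq(pi, 0, length.out = n_arc)
  poly <- rbind(cbind(cx + r_out * cos(th), cy - r_out * sin(th)),
                cbind(cx + r_in * cos(rev(th)), cy - r_in * sin(rev(th))))
  lumen_contour(poly[, 1], poly[, 2], check_simple = FALSE)
}

# Regular polygon approximating a circle (for area tests).
circle_contour <- function(r = 10, n = 64, cx = 0, cy = 0, phase_id = 1L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  lumen_contour(cx + r * cos(th), cy + r * sin(th), phase_id = phase_id)
}

# A constant uniform in-plane velocity field as AP/FH map series.
uniform_field_maps <- function(v_ap, v_fh, nr = 40, nc = 40, nph = 5,
                               spacing = 1, rr = 1) {
  tph <- (seq_len(nph) - 1) * rr / nph
  list(ap = velocity_map_series(replicate(nph, matrix(v_ap, nr, nc),
                                          simplify = FALSE),
                                "AP", c(spacing, spacing), tph, 1.5, rr),
       fh = velocity_map_series(replicate(nph, matrix(v_fh, nr, nc),
                                          simplify = FALSE),
                                "FH", c(spacing, spacing), tph, 1.5, rr))
}

# Site onsets lying exactly on a line onset = t0 + s/pwv (+ optional noise).
linear_site_onsets <- function(s, pwv, t0 = 0.08, noise_sd = 0) {
  onsets <- t0 + s / pwv + if (noise_sd > 0)
    stats::rnorm(length(s), 0, noise_sd) else 0
  lapply(seq_along(s), function(i)
    site_onset(s[i], onset_estimate(onsets[i], baseline_level = 0,
                                    upslope_slope = 10,
                                    upslope_intercept = -1,
                                    n_fit_samples = 4L)))
}

quiet_onset <- function(wf, detect = detect_onset_velocity) {
  tryCatch(detect(wf), aortapwv_error = function(e) NULL)
}

# the unperturbed consistency world: no measurement noise, no jitter, and
# no systematic cuff bias
noiseless_config <- function(seed = 1, ...) {
  cohort_config(seed = seed, onset_jitter_sd_s = 0, velocity_noise_sd = 0,
                cuff_noise_sd = 0, cuff_bias_mmHg = 0, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
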