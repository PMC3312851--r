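#' Unit-amplitude physiologic waveform template
#'
#' Evaluates a strictly monotone-upslope cardiac waveform template at cycle
#' phases in `[0, 1)`. The template is 0 during late diastole and rises
#' linearly from the foot (at `onset_phase`) to a unit peak over
#' `upstroke_frac` of the cycle, so the entire 20-80% band of the upstroke
#' lies on one straight line whose baseline intersection is the configured
#' foot: foot detection by upslope regression is well posed and exact. After
#' the peak it decays smoothly (raised cosine) with an optional dicrotic
#' bump.
#'
#' The `"pressure"` variant decays over the whole diastole and reaches zero
#' exactly at the next foot, so the minimal pressure prior to the systolic
#' upslope falls at the foot, as the pressure onset detector assumes.
#'
#' @param phase Cycle phase(s) in `[0, 1)` (values are wrapped).
#' @param onset_phase Foot position as a fraction of the cycle.
#' @param upstroke_frac Upstroke duration as a fraction of the cycle.
#' @param decay_frac `"velocity"` only: decay duration fraction; the
#'   template is identically 0 afterwards.
#' @param dicrotic_amp Relative amplitude of the dicrotic bump (0 disables).
#' @param kind `"velocity"` or `"pressure"`.
#' @return Numeric template values in `[0, 1]`, peak = 1.
#' @export
waveform_template <- function(phase, onset_phase = 0, upstroke_frac = 0.10,
                              decay_frac = 0.30, dicrotic_amp = 0.12,
                              kind = c("velocity", "pressure")) {
  kind <- match.arg(kind)
  x <- (phase - onset_phase) %% 1
  y <- numeric(length(x))
  up <- x < upstroke_frac
  y[up] <- x[up] / upstroke_frac
  if (kind == "velocity") {
    dec <- !up & x < upstroke_frac + decay_frac
    tau <- (x[dec] - upstroke_frac) / decay_frac
    y[dec] <- 0.5 * (1 + cos(pi * tau)) + dicrotic_amp * sin(pi * tau)^2
  } else {
    dec <- !up
    tau <- (x[dec] - upstroke_frac) / (1 - upstroke_frac)
    base <- 0.5 * (1 + cos(pi * tau))
    bump <- numeric(length(tau))
    inb <- tau >= 0.2 & tau <= 0.6
    bump[inb] <- dicrotic_amp * sin(pi * (tau[inb] - 0.2) / 0.4)^2
    y[dec] <- base + bump
  }
  y
}

#' Cohort generator configuration
#'
#' Default values encode the study conditions the generator emulates:
#' 17 subjects, PWV 7.0 +/- 1.6 m/s, aortic pulse pressure 53 +/- 15 mmHg
#' (129/76 mmHg brachial pressures), 2 kHz pressure sampling over >= 10
#' cardiac cycles during a stepwise pullback on a 5.8 cm grid, ~35-phase
#' velocity-encoded CMR sampling over 200 centerline chords, and a brachial
#' cuff pulse pressure biased 8 mmHg below the central aortic value (cuff
#' sphygmomanometry under-reads the invasive aortic pulse pressure in this
#' population, which is what makes the cuff-based modeled PWV underestimate
#' the pressure-assessed PWV more than the catheter-based one).
#'
#' @param n_subjects Number of subjects.
#' @param seed RNG seed; mandatory for any stochastic run.
#' @param pwv_mean,pwv_sd,pwv_min Local PWV distribution, m/s (normal,
#'   truncated below at `pwv_min`).
#' @param pp_mean,pp_sd,pp_min Aortic pulse pressure distribution, mmHg.
#' @param a_min_mean,a_min_sd,a_min_floor Minimal lumen area, mm^2.
#' @param dbp_mean,dbp_sd Diastolic pressure, mmHg (truncated below 40).
#' @param rr_mean,rr_sd Cycle duration, s (truncated to [0.6, 1.4]).
#' @param rr_jitter_frac Beat-to-beat fractional RR variability of the ECG
#'   trigger sequence in pressure recordings (sinus arrhythmia; this
#'   physiologic timing variability is why several cycles are recorded and
#'   aggregated per pullback position).
#' @param cuff_bias_mmHg,cuff_noise_sd Brachial cuff pulse-pressure bias
#'   and measurement noise, mmHg.
#' @param onset_jitter_sd_s Per-cycle respiratory jitter of the wave-front
#'   foot, s.
#' @param velocity_noise_sd Additive noise on velocity curves, m/s.
#' @param cmr_phases_per_cycle Reconstructed CMR phases per R-R interval.
#' @param pressure_rate_hz Invasive pressure sampling rate, Hz.
#' @param n_cycles_pressure Cardiac cycles recorded per pullback position.
#' @param pullback_positions_m Pullback grid (0.058 m steps).
#' @param site1_m,site2_m Arc positions of the ascending (site 1) and
#'   proximal-descending (site 2) measurement sites, m.
#' @param n_chords Number of centerline sampling chords.
#' @param regional_local_pwv_ratio True arch (regional) PWV divided by the
#'   true descending (local) PWV.
#' @param model_violation_sd SD of a multiplicative log-normal perturbation
#'   of the distensibility used to generate the area series (0 = exactly
#'   model-consistent world).
#' @param foot_time_s Wave-front foot time at arc position 0, s after the
#'   R-wave.
#' @param upstroke_frac,decay_frac,dicrotic_amp Waveform template shape.
#' @param rho Blood density, kg m^-3.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 17L, seed = NULL,
                          pwv_mean = 7.0, pwv_sd = 1.6, pwv_min = 3.0,
                          pp_mean = 53, pp_sd = 15, pp_min = 20,
                          a_min_mean = 450, a_min_sd = 80, a_min_floor = 200,
                          dbp_mean = 76, dbp_sd = 13,
                          rr_mean = 0.95, rr_sd = 0.08,
                          rr_jitter_frac = 0.02,
                          cuff_bias_mmHg = -8, cuff_noise_sd = 4,
                          onset_jitter_sd_s = 0.002,
                          velocity_noise_sd = 0.015,
                          cmr_phases_per_cycle = 35L,
                          pressure_rate_hz = 2000,
                          n_cycles_pressure = 10L,
                          pullback_positions_m = seq(0, 0.29, by = 0.058),
                          site1_m = 0.058, site2_m = 0.174,
                          n_chords = 200L,
                          regional_local_pwv_ratio = 0.95,
                          model_violation_sd = 0,
                          foot_time_s = 0.08,
                          upstroke_frac = 0.10, decay_frac = 0.30,
                          dicrotic_amp = 0.12,
                          rho = 1059) {
  if (n_subjects < 1L)
    pwv_abort("config_error", "n_subjects must be >= 1")
  if (upstroke_frac <= 2 / cmr_phases_per_cycle)
    pwv_abort("config_error",
              "upstroke duration must exceed 2 CMR phase intervals")
  if (n_cycles_pressure < 2L)
    pwv_abort("config_error", "need >= 2 cycles per pressure recording")
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

#' Ground-truth record for one synthetic subject
#'
#' The synthetic world is exactly Bramwell-Hill-consistent: the constructor
#' enforces `D_per_Pa = 1 / (rho * pwv_local^2)`.
#'
#' @param pwv_local_m_per_s True local (descending) PWV, m/s.
#' @param pwv_regional_m_per_s True arch (regional) wavefront speed, m/s.
#' @param pp_aortic_mmHg True aortic pulse pressure, mmHg.
#' @param A_min_mm2 Minimal lumen area, mm^2.
#' @param dbp_mmHg Diastolic pressure, mmHg.
#' @param rr_s Cycle duration, s.
#' @param pp_cuff_mmHg Biased cuff pulse pressure (filled by the simulator).
#' @param D_per_Pa Distensibility; if supplied it must equal
#'   `1/(rho * pwv_local^2)` to 1e-9 relative, else `config_error`.
#' @param rho Blood density, kg m^-3.
#' @return An object of class `subject_truth`.
#' @export
subject_truth <- function(pwv_local_m_per_s, pwv_regional_m_per_s,
                          pp_aortic_mmHg, A_min_mm2, dbp_mmHg, rr_s,
                          pp_cuff_mmHg = NA_real_, D_per_Pa = NULL,
                          rho = 1059) {
  vals <- c(pwv_local_m_per_s, pwv_regional_m_per_s, pp_aortic_mmHg,
            A_min_mm2, dbp_mmHg, rr_s)
  if (!all(is.finite(vals)) || any(vals <= 0))
    pwv_abort("config_error", "all truth fields must be positive")
  D_bh <- 1 / (rho * pwv_local_m_per_s^2)
  if (!is.null(D_per_Pa) &&
      abs(D_per_Pa - D_bh) > 1e-9 * D_bh)
    pwv_abort("config_error",
              "inconsistent truth: D_per_Pa != 1/(rho * pwv_local^2)")
  structure(list(pwv_local_m_per_s = pwv_local_m_per_s,
                 pwv_regional_m_per_s = pwv_regional_m_per_s,
                 D_per_Pa = D_bh, pp_aortic_mmHg = pp_aortic_mmHg,
                 pp_cuff_mmHg = pp_cuff_mmHg, A_min_mm2 = A_min_mm2,
                 dbp_mmHg = dbp_mmHg, rr_s = rr_s, rho = rho),
            class = "subject_truth")
}

#' True wave-front onset time at an arc position
#'
#' The simulated wavefront propagates at the regional (arch) speed up to
#' the start of the local trajectory (`site2_m` - 0.058 m) and at the local
#' (descending) speed beyond it; onset times are the line integrals of the
#' slowness.
#'
#' @param truth A `subject_truth`.
#' @param s_m Arc position(s), m.
#' @param config A `cohort_config`.
#' @return Onset time(s), s after the R-wave.
#' @export
true_onset_time <- function(truth, s_m, config) {
  sb <- config$site2_m - 0.058
  ifelse(s_m <= sb,
         config$foot_time_s + s_m / truth$pwv_regional_m_per_s,
         config$foot_time_s + sb / truth$pwv_regional_m_per_s +
           (s_m - sb) / truth$pwv_local_m_per_s)
}

#' True two-site PWV between arc positions
#'
#' The transit-time-implied speed `(s2 - s1) / (T(s2) - T(s1))` of the
#' simulated (piecewise-constant-speed) wavefront; the reference value for
#' regional recovery checks.
#'
#' @inheritParams true_onset_time
#' @param s1_m,s2_m Arc positions, m.
#' @return Speed in m/s.
#' @export
true_two_site_pwv <- function(truth, s1_m, s2_m, config) {
  abs(s2_m - s1_m) /
    abs(true_onset_time(truth, s2_m, config) -
          true_onset_time(truth, s1_m, config))
}

# one pullback pressure recording at arc position s; the ECG trigger
# sequence carries beat-to-beat RR variability (sinus arrhythmia)
.simulate_pressure_recording <- function(truth, config, s_m) {
  fs <- config$pressure_rate_hz
  rr <- truth$rr_s
  ncyc <- config$n_cycles_pressure
  rr_k <- rr * pmax(0.5, 1 + stats::rnorm(ncyc, 0, config$rr_jitter_frac))
  trig <- c(0, cumsum(rr_k))
  t <- seq(0, trig[ncyc + 1L] + 2 / fs, by = 1 / fs)
  T_s <- true_onset_time(truth, s_m, config)
  jit <- stats::rnorm(ncyc, 0, config$onset_jitter_sd_s)
  cyc <- pmin(findInterval(t, trig), ncyc)     # samples past last trigger
  phase <- (t - trig[cyc]) / rr_k[cyc]         # stay in the final cycle
  foot_phase <- (T_s + jit[cyc]) / rr_k[cyc]
  vals <- truth$dbp_mmHg + truth$pp_aortic_mmHg *
    waveform_template(phase, onset_phase = foot_phase,
                      upstroke_frac = config$upstroke_frac,
                      dicrotic_amp = config$dicrotic_amp,
                      kind = "pressure")
  multicycle_recording(
    sampled_waveform(vals, sample_interval_s = 1 / fs, start_time_s = 0,
                     kind = "pressure", rr_s = rr),
    r_wave_times_s = trig, site_position_m = s_m)
}

# velocity-time curve at arc position s on the CMR phase grid
.simulate_velocity_curve <- function(truth, config, s_m, amp, noise_sd) {
  rr <- truth$rr_s
  nph <- config$cmr_phases_per_cycle
  tph <- (seq_len(nph) - 1L) * rr / nph
  T_s <- true_onset_time(truth, s_m, config)
  v <- amp * waveform_template((tph %% rr) / rr, onset_phase = T_s / rr,
                               upstroke_frac = config$upstroke_frac,
                               decay_frac = config$decay_frac,
                               dicrotic_amp = config$dicrotic_amp,
                               kind = "velocity")
  if (noise_sd > 0) v <- v + stats::rnorm(nph, 0, noise_sd)
  sampled_waveform(v, sample_interval_s = rr / nph, start_time_s = 0,
                   kind = "velocity", rr_s = rr)
}

#' Simulate one subject's measurement set
#'
#' Generates, from one ground-truth record: (a) the stepwise pressure
#' pullback (2 kHz, >= 10 cycles per position, per-cycle respiratory onset
#' jitter); (b) the 200 per-chord velocity-time curves on the CMR phase
#' grid with additive noise; (c) through-plane-style maximal velocity
#' curves at sites 1 and 2; (d) a per-phase lumen area series generated
#' from the linearized area-pressure relation
#' `A(t) = A_min * (1 + D * deltaP(t) * 133.322)` whose sampled distension
#' spans the full pulse pressure (so the distensibility recovered from the
#' emitted series is exact in the noiseless limit); (e) the local pressure
#' curve on the CMR phase grid; and (f) a biased brachial-cuff pulse
#' pressure. The truth record (with the drawn cuff value) is attached.
#'
#' @param truth A `subject_truth`.
#' @param config A `cohort_config`.
#' @return A list of class `subject_dataset`.
#' @export
simulate_subject <- function(truth, config) {
  stopifnot(inherits(truth, "subject_truth"),
            inherits(config, "cohort_config"))
  rr <- truth$rr_s
  nph <- config$cmr_phases_per_cycle
  tph <- (seq_len(nph) - 1L) * rr / nph

  pullback <- lapply(config$pullback_positions_m, function(s)
    .simulate_pressure_recording(truth, config, s))

  amp <- 1.0 * (1 + stats::runif(1, -0.2, 0.2))
  chord_pos <- seq(0, max(config$pullback_positions_m),
                   length.out = config$n_chords)
  chords <- lapply(chord_pos, function(s)
    .simulate_velocity_curve(truth, config, s, amp,
                             config$velocity_noise_sd))
  attr(chords, "arc_positions_m") <- chord_pos

  tp_curves <- list(
    site1 = .simulate_velocity_curve(truth, config, config$site1_m, amp,
                                     config$velocity_noise_sd),
    site2 = .simulate_velocity_curve(truth, config, config$site2_m, amp,
                                     config$velocity_noise_sd))

  # local pressure at site 2 on the CMR phase grid
  T2 <- true_onset_time(truth, config$site2_m, config)
  p_cmr <- truth$dbp_mmHg + truth$pp_aortic_mmHg *
    waveform_template((tph %% rr) / rr, onset_phase = T2 / rr,
                      upstroke_frac = config$upstroke_frac,
                      dicrotic_amp = config$dicrotic_amp, kind = "pressure")
  pressure_local_cmr <- sampled_waveform(p_cmr, sample_interval_s = rr / nph,
                                         start_time_s = 0, kind = "pressure",
                                         rr_s = rr)

  # area series: linearized area-pressure relation; the distension waveform
  # has a flat zero diastole and is normalized to its sampled maximum so the
  # emitted series attains both A_min and A_min + delta_A exactly
  D_eff <- truth$D_per_Pa *
    exp(if (config$model_violation_sd > 0)
      stats::rnorm(1, 0, config$model_violation_sd) else 0)
  u <- waveform_template((tph %% rr) / rr, onset_phase = T2 / rr,
                         upstroke_frac = config$upstroke_frac,
                         decay_frac = config$decay_frac,
                         dicrotic_amp = config$dicrotic_amp,
                         kind = "velocity")
  u <- u / max(u)
  area_vals <- truth$A_min_mm2 *
    (1 + D_eff * truth$pp_aortic_mmHg * MMHG_TO_PA * u)
  area <- sampled_waveform(area_vals, sample_interval_s = rr / nph,
                           start_time_s = 0, kind = "area", rr_s = rr)

  pp_cuff <- truth$pp_aortic_mmHg + config$cuff_bias_mmHg +
    stats::rnorm(1, 0, config$cuff_noise_sd)
  truth$pp_cuff_mmHg <- pp_cuff

  structure(list(pullback = pullback, chords = chords,
                 tp_curves = tp_curves, area = area,
                 pressure_local_cmr = pressure_local_cmr,
                 pp_cuff_mmHg = pp_cuff, D_effective_per_Pa = D_eff,
                 truth = truth),
            class = "subject_dataset")
}

# normal draw truncated below (vector), by redrawing
.rnorm_trunc <- function(n, mean, sd, lower, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Simulate a study cohort with known ground truth
#'
#' Draws per-subject truths (local PWV ~ Normal truncated at 3 m/s, aortic
#' pulse pressure truncated at 20 mmHg, minimal area truncated at 200 mm^2,
#' regional speed = ratio * local speed) and simulates every subject's
#' measurement set. Fully reproducible from `config$seed`.
#'
#' @param config A `cohort_config` with a non-`NULL` seed.
#' @return A list of class `pwv_cohort` with `config`, `truth` (data frame,
#'   one row per subject) and `subjects` (list of `subject_dataset`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(config$seed))
    pwv_abort("config_error", "a seed is mandatory for any stochastic run")
  set.seed(as.integer(config$seed))
  n <- config$n_subjects
  pwv_local <- .rnorm_trunc(n, config$pwv_mean, config$pwv_sd, config$pwv_min)
  pp <- .rnorm_trunc(n, config$pp_mean, config$pp_sd, config$pp_min)
  a_min <- .rnorm_trunc(n, config$a_min_mean, config$a_min_sd,
                        config$a_min_floor)
  dbp <- .rnorm_trunc(n, config$dbp_mean, config$dbp_sd, 40)
  rr <- .rnorm_trunc(n, config$rr_mean, config$rr_sd, 0.6, 1.4)
  subjects <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- subject_truth(pwv_local_m_per_s = pwv_local[i],
                        pwv_regional_m_per_s =
                          config$regional_local_pwv_ratio * pwv_local[i],
                        pp_aortic_mmHg = pp[i], A_min_mm2 = a_min[i],
                        dbp_mmHg = dbp[i], rr_s = rr[i], rho = config$rho)
    subjects[[i]] <- simulate_subject(tr, config)
    tru <- subjects[[i]]$truth
    rows[[i]] <- data.frame(subject = i,
                            pwv_local_m_per_s = tru$pwv_local_m_per_s,
                            pwv_regional_m_per_s = tru$pwv_regional_m_per_s,
                            D_per_Pa = tru$D_per_Pa,
                            pp_aortic_mmHg = tru$pp_aortic_mmHg,
                            pp_cuff_mmHg = tru$pp_cuff_mmHg,
                            A_min_mm2 = tru$A_min_mm2,
                            dbp_mmHg = tru$dbp_mmHg, rr_s = tru$rr_s)
  }
  structure(list(config = config, truth = do.call(rbind, rows),
                 subjects = subjects),
            class = "pwv_cohort")
}

#' Rasterize an in-plane velocity-map phantom for one subject
#'
#' Builds a composite aortic-arch phantom — a half-annulus arch (centerline
#' radius `arch_radius_mm`) joined to a straight descending segment — with a
#' parabolic cross-lumen velocity profile directed along the local tangent
#' and amplitude following the delayed waveform template (delay = arc
#' position / PWV, uniform at the subject's local PWV). The field is split
#' into AP and FH component series, clipped to the encoding limit, and the
#' lumen polygon is emitted as the ground-truth contour together with the
#' endpoint hints for centerline extraction.
#'
#' @param truth A `subject_truth`.
#' @param config A `cohort_config`.
#' @param pixel_mm Pixel spacing, mm (isotropic).
#' @param arch_radius_mm Arch centerline radius.
#' @param halfwidth_mm Lumen half-width.
#' @param desc_length_mm Length of the straight descending segment.
#' @param venc_m_per_s Velocity-encoding limit.
#' @param amp Peak centerline velocity, m/s.
#' @param noise_sd Additive per-pixel velocity noise, m/s (0 = noiseless).
#' @param n_arc_points Vertices per contour arc.
#' @return List with `maps_ap`, `maps_fh` (`velocity_map_series`),
#'   `contour` (`lumen_contour`), `hint_start`, `hint_end`,
#'   `arc_length_true_m`, and `pwv_true_m_per_s`.
#' @export
rasterize_maps <- function(truth, config, pixel_mm = 1,
                           arch_radius_mm = 35, halfwidth_mm = 10,
                           desc_length_mm = 60, venc_m_per_s = 1.5,
                           amp = 1.0, noise_sd = 0, n_arc_points = 90L) {
  stopifnot(inherits(truth, "subject_truth"),
            inherits(config, "cohort_config"))
  R <- arch_radius_mm; hw <- halfwidth_mm
  cx <- R + hw + 10; cy <- R + hw / 2 + 10
  xmax <- cx + R + hw + 10
  ymax <- cy + desc_length_mm + 10
  if (R - hw <= 0)
    pwv_abort("config_error", "lumen half-width exceeds the arch radius")
  gx <- seq(0, xmax, by = pixel_mm)
  gy <- seq(0, ymax, by = pixel_mm)
  nc <- length(gx); nr <- length(gy)
  X <- matrix(rep(gx, each = nr), nr, nc)
  Y <- matrix(rep(gy, times = nc), nr, nc)

  # arch (upper half-annulus, image y grows downward)
  rad <- sqrt((X - cx)^2 + (Y - cy)^2)
  theta <- atan2(cy - Y, X - cx)
  in_arch <- Y <= cy & rad >= R - hw & rad <= R + hw
  # descending straight segment
  in_desc <- Y > cy & Y <= cy + desc_length_mm &
    X >= cx + R - hw & X <= cx + R + hw

  S <- matrix(NA_real_, nr, nc)                 # arc position, mm
  D <- matrix(NA_real_, nr, nc)                 # signed radial offset, mm
  TX <- matrix(0, nr, nc); TY <- matrix(0, nr, nc)
  S[in_arch] <- (pi - theta[in_arch]) * R
  D[in_arch] <- rad[in_arch] - R
  TX[in_arch] <- sin(theta[in_arch])
  TY[in_arch] <- cos(theta[in_arch])
  S[in_desc] <- pi * R + (Y[in_desc] - cy)
  D[in_desc] <- X[in_desc] - (cx + R)
  TX[in_desc] <- 0
  TY[in_desc] <- 1
  mask <- in_arch | in_desc
  prof <- matrix(0, nr, nc)
  prof[mask] <- 1 - (D[mask] / hw)^2

  if (max(gx) < cx + R + hw || max(gy) < cy + desc_length_mm)
    pwv_abort("config_error", "phantom exceeds the image grid")

  rr <- truth$rr_s
  nph <- config$cmr_phases_per_cycle
  tph <- (seq_len(nph) - 1L) * rr / nph
  pwv <- truth$pwv_local_m_per_s
  delay <- S / 1000 / pwv

  frames_ap <- vector("list", nph)
  frames_fh <- vector("list", nph)
  for (p in seq_len(nph)) {
    v <- matrix(0, nr, nc)
    ph <- ((tph[p] - config$foot_time_s - delay[mask]) %% rr) / rr
    v[mask] <- amp * prof[mask] *
      waveform_template(ph, onset_phase = 0,
                        upstroke_frac = config$upstroke_frac,
                        decay_frac = config$decay_frac,
                        dicrotic_amp = config$dicrotic_amp,
                        kind = "velocity")
    if (noise_sd > 0) v[mask] <- v[mask] + stats::rnorm(sum(mask), 0, noise_sd)
    v <- pmin(pmax(v, -venc_m_per_s), venc_m_per_s)
    frames_ap[[p]] <- v * TY
    frames_fh[[p]] <- v * TX
  }
  # ground-truth lumen polygon: outer arc, descending outer edge, bottom,
  # descending inner edge, inner arc, ascending end edge
  th <- seq(pi, 0, length.out = n_arc_points)
  outer <- cbind(cx + (R + hw) * cos(th), cy - (R + hw) * sin(th))
  inner <- cbind(cx + (R - hw) * cos(rev(th)), cy - (R - hw) * sin(rev(th)))
  ybot <- cy + desc_length_mm
  poly <- rbind(outer,
                c(cx + R + hw, ybot), c(cx + R - hw, ybot),
                inner)
  contour <- lumen_contour(poly[, 1], poly[, 2], check_simple = FALSE)
  list(maps_ap = velocity_map_series(frames_ap, "AP",
                                     pixel_spacing_mm = c(pixel_mm, pixel_mm),
                                     phase_times_s = tph,
                                     venc_m_per_s = venc_m_per_s, rr_s = rr),
       maps_fh = velocity_map_series(frames_fh, "FH",
                                     pixel_spacing_mm = c(pixel_mm, pixel_mm),
                                     phase_times_s = tph,
                                     venc_m_per_s = venc_m_per_s, rr_s = rr),
       contour = contour,
       hint_start = c(cx - R, cy), hint_end = c(cx + R, cy + desc_length_mm),
       arc_length_true_m = (pi * R + desc_length_mm) / 1000,
       pwv_true_m_per_s = pwv)
}
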