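test_that("waveform template anchors: zero before the foot, unit peak", {
  expect_equal(waveform_template(0.05, onset_phase = 0.1), 0)
  expect_equal(waveform_template(0.1 + 0.10, onset_phase = 0.1), 1)
  expect_equal(waveform_template(0.95, onset_phase = 0.1), 0)
  ph <- seq(0, 0.999, by = 1e-3)
  vel <- waveform_template(ph, onset_phase = 0.1)
  expect_true(all(vel >= 0 & vel <= 1))
  # pressure variant decays strictly to zero exactly at the next foot
  pre <- waveform_template(ph, onset_phase = 0, kind = "pressure")
  expect_equal(max(pre), 1)
  expect_lt(pre[1000], 1e-4)
  tail <- pre[ph > 0.7]
  expect_true(all(diff(tail) < 0))
})

test_that("template foot is recovered within 1 ms at 2 kHz", {
  fs <- 2000; rr <- 0.93
  t <- seq(0, rr - 1 / fs, by = 1 / fs)
  for (foot in c(0.080, 0.1234)) {
    v <- waveform_template(t / rr, onset_phase = foot / rr)
    o <- detect_onset_velocity(sampled_waveform(v, 1 / fs, 0, "velocity", rr))
    expect_lt(abs(o$onset_s - foot), 1e-3)
  }
})

test_that("configurations violating the sampling contract are rejected", {
  expect_error(cohort_config(seed = 1, upstroke_frac = 0.05,
                             cmr_phases_per_cycle = 35),
               class = "aortapwv_config_error")
  expect_error(cohort_config(n_subjects = 0, seed = 1),
               class = "aortapwv_config_error")
  expect_error(simulate_cohort(cohort_config()),
               class = "aortapwv_config_error")   # seed mandatory
  expect_error(subject_truth(7, 6.65, 50, 400, 76, 0.9,
                             D_per_Pa = 2 / (1059 * 49)),
               class = "aortapwv_config_error")   # inconsistent truth
  # consistent explicit D is accepted
  tr <- subject_truth(7, 6.65, 50, 400, 76, 0.9, D_per_Pa = 1 / (1059 * 49))
  expect_equal(tr$D_per_Pa, 1 / (1059 * 7^2))
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- cohort_config(n_subjects = 3, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("truth draws respect their truncation bounds", {
  coh <- simulate_cohort(cohort_config(n_subjects = 300, seed = 7,
                                       pwv_mean = 4, pwv_sd = 2))
  expect_gte(min(coh$truth$pwv_local_m_per_s), 3)
  expect_gte(min(coh$truth$pp_aortic_mmHg), 20)
  expect_gte(min(coh$truth$A_min_mm2), 200)
  # the subject-level invariant holds for every row
  expect_equal(coh$truth$D_per_Pa,
               1 / (1059 * coh$truth$pwv_local_m_per_s^2), tolerance = 1e-12)
})

test_that("a noiseless subject is recovered by the measurement pipeline", {
  cfg <- noiseless_config()
  set.seed(12)
  tr <- subject_truth(7.0, 0.95 * 7.0, 50, 400, 76, 0.97)
  subj <- simulate_subject(tr, cfg)
  # local multi-site PWV from the generated chords
  pos <- attr(subj$chords, "arc_positions_m")
  sites <- lapply(seq_along(pos), function(i)
    site_onset(pos[i], detect_onset_velocity(subj$chords[[i]])))
  est <- multi_site_pwv(sites, window = c(cfg$site2_m - 0.058,
                                          cfg$site2_m + 0.058))
  expect_lt(abs(est$pwv_m_per_s / 7 - 1), 0.03)
  # distensibility from the emitted area series is exact
  a <- subj$area$values
  d <- distensibility(max(a) - min(a), min(a), tr$pp_aortic_mmHg)
  expect_equal(d$D_per_Pa, tr$D_per_Pa, tolerance = 1e-9)
  # and the regional wavefront follows the piecewise speed field
  reg <- pullback_pwv(subj$pullback, "regional", site1_m = cfg$site1_m,
                      site2_m = cfg$site2_m)
  expect_lt(abs(reg$pwv_m_per_s /
                  true_two_site_pwv(tr, cfg$site1_m, cfg$site2_m, cfg) - 1),
            0.01)
})

test_that("onset-time field is piecewise linear in arc length", {
  cfg <- cohort_config(seed = 1)
  tr <- subject_truth(8, 0.9 * 8, 50, 400, 76, 0.9)
  sb <- cfg$site2_m - 0.058
  s <- c(0, sb / 2, sb, sb + 0.01, sb + 0.1)
  tt <- true_onset_time(tr, s, cfg)
  expect_equal(diff(tt)[1:2] / diff(s)[1:2],
               rep(1 / tr$pwv_regional_m_per_s, 2), tolerance = 1e-12)
  expect_equal(diff(tt)[3:4] / diff(s)[3:4],
               rep(1 / tr$pwv_local_m_per_s, 2), tolerance = 1e-12)
  expect_equal(true_two_site_pwv(tr, sb, sb + 0.1, cfg),
               tr$pwv_local_m_per_s, tolerance = 1e-12)
})

test_that("a smaller pulse pressure in the model lowers the modeled PWV", {
  # under-reading the pulse pressure inflates the distensibility estimate
  # and lowers the Bramwell-Hill PWV, so a negative cuff bias makes the
  # cuff-based modeled PWV underestimate relative to the catheter-based one
  d_cath <- distensibility(50, 400, 50)
  d_cuff <- distensibility(50, 400, 42)
  expect_gt(d_cuff$D_per_Pa, d_cath$D_per_Pa)
  expect_lt(theoretical_pwv(d_cuff), theoretical_pwv(d_cath))
})

test_that("cuff pulse pressure carries the configured bias", {
  coh <- simulate_cohort(cohort_config(n_subjects = 40, seed = 21))
  bias <- coh$truth$pp_cuff_mmHg - coh$truth$pp_aortic_mmHg
  expect_lt(abs(mean(bias) - (-8)), 2)
  expect_gt(sd(bias), 1)
})

test_that("rasterized phantom respects the encoding limit and its geometry", {
  cfg <- noiseless_config()
  tr <- subject_truth(7, 6.65, 50, 400, 76, 0.95)
  ph <- rasterize_maps(tr, cfg)
  vmax <- max(vapply(seq_along(ph$maps_ap$frames), function(p)
    max(abs(ph$maps_ap$frames[[p]])^2 + abs(ph$maps_fh$frames[[p]])^2),
    numeric(1)))
  expect_lte(sqrt(vmax), 1.5 + 1e-9)
  expect_s3_class(ph$contour, "lumen_contour")
  expect_equal(ph$arc_length_true_m, (pi * 35 + 60) / 1000, tolerance = 1e-12)
  expect_error(rasterize_maps(tr, cfg, halfwidth_mm = 40),
               class = "aortapwv_config_error")
})
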