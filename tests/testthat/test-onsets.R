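test_that("velocity onset equals the analytic line intersection", {
  cyc <- piecewise_velocity_cycle()
  o <- detect_onset_velocity(cyc)
  expect_true(o$valid)
  expect_equal(o$onset_s, 0.100, tolerance = 1e-6)
  expect_equal(o$baseline_level, 0.05, tolerance = 1e-9)
  expect_equal(o$upslope_slope, 8, tolerance = 1e-6)
  expect_gte(o$n_fit_samples, 3L)
})

test_that("flat curves raise the no-upslope error", {
  flat <- sampled_waveform(rep(0.05, 1000), 5e-4, 0, "velocity", 0.5)
  expect_error(detect_onset_velocity(flat), class = "aortapwv_no_upslope_error")
  zero <- sampled_waveform(rep(0, 35), 1 / 35, 0, "velocity", 1)
  expect_error(detect_onset_velocity(zero), class = "aortapwv_no_upslope_error")
})

test_that("mean onset over noisy replicates stays within 5 ms of truth", {
  set.seed(101)
  onsets <- replicate(200, {
    cyc <- piecewise_velocity_cycle()
    cyc$values <- cyc$values + rnorm(length(cyc$values), 0, 0.02)
    o <- quiet_onset(cyc)
    if (is.null(o) || !o$valid) NA_real_ else o$onset_s
  })
  expect_lt(mean(is.na(onsets)), 0.05)
  expect_lt(abs(mean(onsets, na.rm = TRUE) - 0.100), 0.005)
})

test_that("velocity onset is invariant to amplitude scaling", {
  for (k in c(0.2, 1, 3.7, 10)) {
    cyc <- piecewise_velocity_cycle()
    cyc$values <- k * cyc$values
    expect_equal(detect_onset_velocity(cyc)$onset_s, 0.100,
                 tolerance = 1e-6, label = sprintf("k = %g", k))
  }
})

test_that("onsets are equivariant under time shifts", {
  base <- detect_onset_velocity(piecewise_velocity_cycle())$onset_s
  basep <- detect_onset_pressure(pressure_cycle())$onset_s
  for (delta in c(-0.05, 0.01, 0.2)) {
    cyc <- piecewise_velocity_cycle()
    cyc$start_time_s <- cyc$start_time_s + delta
    expect_equal(detect_onset_velocity(cyc)$onset_s, base + delta,
                 tolerance = 1e-9)
    pcy <- pressure_cycle()
    pcy$start_time_s <- pcy$start_time_s + delta
    expect_equal(detect_onset_pressure(pcy)$onset_s, basep + delta,
                 tolerance = 1e-9)
  }
})

test_that("closed-form intersection matches a 1 us brute-force grid search", {
  # oracle: evaluate the two fitted lines on a 1 us grid and find where the
  # upslope line first meets the baseline
  set.seed(77)
  for (rep in 1:100) {
    cyc <- piecewise_velocity_cycle(base = runif(1, 0, 0.1),
                                    foot = runif(1, 0.05, 0.2),
                                    slope = runif(1, 4, 15),
                                    peak = runif(1, 0.6, 1.2))
    o <- detect_onset_velocity(cyc)
    tg <- seq(o$onset_s - 0.01, o$onset_s + 0.01, by = 1e-6)
    line <- o$upslope_intercept + o$upslope_slope * tg
    t_bf <- tg[which.min(abs(line - o$baseline_level))]
    expect_lt(abs(t_bf - o$onset_s), 1e-6)
  }
})

test_that("pressure onset is the pre-peak argmin with the earliest-sample tie-break", {
  o <- detect_onset_pressure(pressure_cycle(foot = 0.08))
  expect_equal(o$onset_s, 0.080, tolerance = 1e-3)
  expect_true(o$valid)
  # direct argmin oracle on random unimodal-ish cycles
  set.seed(13)
  for (rep in 1:20) {
    cyc <- pressure_cycle(foot = runif(1, 0.03, 0.25), rr = runif(1, 0.7, 1.2))
    cyc$values <- cyc$values + rnorm(length(cyc$values), 0, 0.3)
    o <- detect_onset_pressure(cyc)
    pk <- which.max(cyc$values)
    expect_equal(o$onset_s, wf_times(cyc)[which.min(cyc$values[1:pk])])
  }
  # monotone-increasing cycle: onset at the first sample, flagged but valid
  up <- sampled_waveform(seq(80, 120, length.out = 500), 1e-3, 0,
                         "pressure", 0.5)
  o_up <- detect_onset_pressure(up)
  expect_true(o_up$valid)
  expect_equal(o_up$onset_s, 0)
  expect_equal(o_up$reason, "min_at_cycle_start")
  # monotone-decreasing: no peak after a minimum
  down <- sampled_waveform(seq(120, 80, length.out = 500), 1e-3, 0,
                           "pressure", 0.5)
  expect_error(detect_onset_pressure(down),
               class = "aortapwv_no_upslope_error")
  # ties resolve to the earliest sample
  v <- c(90, 85, 85, 95, 110, 100)
  tie <- sampled_waveform(v, 0.1, 0, "pressure", 0.6)
  expect_equal(detect_onset_pressure(tie)$onset_s, 0.1)
})

test_that("onset aggregation uses the median and reports valid-cycle counts", {
  est <- function(x) onset_estimate(x)
  expect_equal(aggregate_onsets(list(est(0.080), est(0.082),
                                     est(0.078)))$onset_s, 0.080)
  expect_equal(aggregate_onsets(list(est(0.091)))$onset_s, 0.091)
  # gross outlier: median within 2 ms of the 9-cycle truth
  set.seed(5)
  clean <- 0.080 + rnorm(9, 0, 0.001)
  all10 <- c(clean, 0.180)
  agg <- aggregate_onsets(lapply(all10, est))
  expect_lt(abs(agg$onset_s - median(clean)), 0.002)
  expect_equal(agg$n_cycles, 10L)
  # invalid estimates are dropped; none valid is an error
  bad <- onset_estimate(NA_real_, valid = FALSE, reason = "x")
  expect_equal(aggregate_onsets(list(bad, est(0.07)))$n_cycles, 1L)
  expect_error(aggregate_onsets(list(bad)),
               class = "aortapwv_aggregation_error")
  # mean is available behind the flag
  expect_equal(aggregate_onsets(list(est(0.06), est(0.10)),
                                method = "mean")$onset_s, 0.08)
})
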