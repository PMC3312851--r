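# Per-subject measurement pipeline: every PWV variant, the pulse pressures,
# and the distensibility-model quantities. Returns a one-row data frame.
.analyze_subject <- function(subj, config, constants) {
  stopifnot(inherits(subj, "subject_dataset"))
  s1 <- config$site1_m
  s2 <- config$site2_m

  pwv_pressure_regional <- pullback_pwv(subj$pullback, "regional",
                                        site1_m = s1, site2_m = s2)$pwv_m_per_s
  pwv_pressure_local <- pullback_pwv(subj$pullback, "local",
                                     center_m = s2)$pwv_m_per_s

  # through-plane: foot-to-foot between the two site velocity curves
  o1 <- detect_onset_velocity(subj$tp_curves$site1)
  o2 <- detect_onset_velocity(subj$tp_curves$site2)
  pwv_tp_regional <- two_site_pwv(site_onset(s1, o1),
                                  site_onset(s2, o2))$pwv_m_per_s

  # in-plane: onset per chord, regression of onset on arc position
  pos <- attr(subj$chords, "arc_positions_m")
  sites <- lapply(seq_along(subj$chords), function(i) {
    est <- tryCatch(detect_onset_velocity(subj$chords[[i]]),
                    aortapwv_error = function(e)
                      onset_estimate(NA_real_, valid = FALSE,
                                     reason = conditionMessage(e)))
    site_onset(pos[i], est)
  })
  pwv_ip_regional <- multi_site_pwv(sites, window = c(s1, s2))$pwv_m_per_s
  pwv_ip_local <- multi_site_pwv(sites,
                                 window = c(s2 - 0.058, s2 + 0.058))$pwv_m_per_s

  # local pulse pressure from the pullback recording nearest site 2
  ppos <- vapply(subj$pullback, function(r) r$site_position_m, numeric(1))
  rec2 <- subj$pullback[[which.min(abs(ppos - s2))]]
  pp_cath <- stats::median(vapply(segment_cycles(rec2), function(cy)
    max(cy$values) - min(cy$values), numeric(1)))

  a <- subj$area$values
  delta_A <- max(a) - min(a)
  A_min <- min(a)
  d_cath <- distensibility(delta_A, A_min, pp_cath)
  d_cuff <- distensibility(delta_A, A_min, subj$pp_cuff_mmHg)

  data.frame(
    pwv_pressure_regional = pwv_pressure_regional,
    pwv_pressure_local = pwv_pressure_local,
    pwv_tp_regional = pwv_tp_regional,
    pwv_ip_regional = pwv_ip_regional,
    pwv_ip_local = pwv_ip_local,
    pp_cath_mmHg = pp_cath,
    pp_cuff_mmHg = subj$pp_cuff_mmHg,
    delta_A_mm2 = delta_A, A_min_mm2 = A_min,
    D_cath_per_Pa = d_cath$D_per_Pa,
    D_cuff_per_Pa = d_cuff$D_per_Pa,
    pwv_bh_cath = theoretical_pwv(d_cath, constants),
    pwv_bh_cuff = theoretical_pwv(d_cuff, constants))
}

#' Run the full method-comparison study on a cohort
#'
#' Computes, per subject, the regional and local pressure (pullback) PWV,
#' the through-plane and in-plane velocity PWV, the local distensibility
#' with both pulse-pressure sources (catheter and cuff), and the modeled
#' (Bramwell-Hill) PWV; then assembles the paired method-agreement reports
#' against the pressure reference, the association table between every PWV
#' variant and distensibility^(-1/2), and the interaction-regression
#' correlation contrasts. Subjects failing any stage are excluded listwise
#' with a logged reason; the run continues if >= 3 remain.
#'
#' @param cohort A `pwv_cohort` from [simulate_cohort()] or
#'   [read_cohort()].
#' @param constants A `blood_constants` object.
#' @return An object of class `study_report`.
#' @export
run_study <- function(cohort, constants = blood_constants()) {
  stopifnot(inherits(cohort, "pwv_cohort"))
  config <- cohort$config
  n_all <- length(cohort$subjects)
  rows <- vector("list", n_all)
  dropped <- character(0)
  for (i in seq_len(n_all)) {
    rows[[i]] <- tryCatch(
      cbind(data.frame(subject = i),
            .analyze_subject(cohort$subjects[[i]], config, constants)),
      aortapwv_error = function(e) {
        dropped <<- c(dropped, sprintf("subject %d: %s", i,
                                       conditionMessage(e)))
        NULL
      })
  }
  per_subject <- do.call(rbind, rows)
  if (is.null(per_subject) || nrow(per_subject) < 3L)
    pwv_abort("sample_size_error",
              "fewer than 3 subjects survived the pipeline")

  ps <- function(test, ref) paired_series(per_subject[[test]],
                                          per_subject[[ref]],
                                          labels = per_subject$subject)
  comparisons <- list(
    tp_regional_vs_pressure = agreement(ps("pwv_tp_regional",
                                           "pwv_pressure_regional")),
    ip_regional_vs_pressure = agreement(ps("pwv_ip_regional",
                                           "pwv_pressure_regional")),
    ip_local_vs_pressure = agreement(ps("pwv_ip_local",
                                        "pwv_pressure_local")),
    bh_cuff_vs_pressure = agreement(ps("pwv_bh_cuff", "pwv_pressure_local")),
    bh_cath_vs_pressure = agreement(ps("pwv_bh_cath", "pwv_pressure_local")))

  # association of each PWV variant with distensibility^(-1/2)
  assoc <- do.call(rbind, lapply(
    c("pwv_tp_regional", "pwv_ip_regional", "pwv_pressure_regional",
      "pwv_ip_local", "pwv_pressure_local"),
    function(v) {
      row <- lapply(c(cuff = "D_cuff_per_Pa", cath = "D_cath_per_Pa"),
                    function(dcol) {
                      x <- per_subject[[v]]
                      y <- per_subject[[dcol]]^(-0.5)
                      ct <- stats::cor.test(x, y)
                      c(r = unname(ct$estimate), p = ct$p.value)
                    })
      data.frame(pwv = v, r_cuff = row$cuff["r"], p_cuff = row$cuff["p"],
                 r_cath = row$cath["r"], p_cath = row$cath["p"],
                 row.names = NULL)
    }))

  contrasts <- list(
    tp_vs_ip_regional = compare_method_correlations(
      ps("pwv_tp_regional", "pwv_pressure_regional"),
      ps("pwv_ip_regional", "pwv_pressure_regional"))$p_interaction,
    bh_cuff_vs_bh_cath = compare_method_correlations(
      ps("pwv_bh_cuff", "pwv_pressure_local"),
      ps("pwv_bh_cath", "pwv_pressure_local"))$p_interaction)

  structure(list(per_subject = per_subject, comparisons = comparisons,
                 bh_association = assoc, correlation_contrasts = contrasts,
                 n_analyzed = nrow(per_subject), dropped = dropped,
                 seed = config$seed, config_hash = config_hash(config)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> n = %d subjects (dropped: %d)\n",
              x$n_analyzed, length(x$dropped)))
  for (nm in names(x$comparisons)) {
    a <- x$comparisons[[nm]]
    cat(sprintf("  %-26s r = %.2f  COV = %.0f%%  mean diff = %+.2f +/- %.2f m/s\n",
                nm, a$pearson_r, a$cov_pct, a$mean_diff, a$sd_diff))
  }
  invisible(x)
}

#' Stable hash of a configuration (provenance stamp)
#' @param config Any serializable object.
#' @return MD5 hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}

# flatten an agreement report to a one-row data frame
.agreement_row <- function(name, a) {
  data.frame(comparison = name, n = a$n, pearson_r = a$pearson_r,
             p_r = a$p_r, cov_pct = a$cov_pct, mue_pct = a$mue_pct,
             mue_sd_pct = a$mue_sd_pct, mean_diff = a$mean_diff,
             sd_diff = a$sd_diff, p_ttest = a$p_ttest,
             ci95_lo = a$ci95_lo, ci95_hi = a$ci95_hi,
             loa_lo = a$loa_lo, loa_hi = a$loa_hi)
}

#' Write a study report to disk (JSON + CSV + plots)
#'
#' Writes `report.json` (full report), `per_subject.csv`,
#' `comparisons.csv` (one row per paired comparison),
#' `bh_association.csv`, and Bland-Altman / scatter plots as PNG side
#' artifacts. Every file carries the config hash and seed for provenance.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @param plots Write PNG plots?
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir, plots = TRUE) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp <- do.call(rbind, Map(.agreement_row, names(report$comparisons),
                             report$comparisons))
  comp$config_hash <- report$config_hash
  comp$seed <- report$seed
  utils::write.csv(comp, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  ps <- report$per_subject
  ps$config_hash <- report$config_hash
  utils::write.csv(ps, file.path(dir, "per_subject.csv"), row.names = FALSE)
  ba <- report$bh_association
  ba$config_hash <- report$config_hash
  utils::write.csv(ba, file.path(dir, "bh_association.csv"),
                   row.names = FALSE)
  json <- list(seed = report$seed, config_hash = report$config_hash,
               n_analyzed = report$n_analyzed, dropped = report$dropped,
               comparisons = lapply(report$comparisons, unclass),
               bh_association = report$bh_association,
               correlation_contrasts = report$correlation_contrasts)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (plots) {
    for (nm in names(report$comparisons)) {
      a <- report$comparisons[[nm]]
      test_col <- sub("_vs_.*", "", nm)
      grDevices::png(file.path(dir, paste0(nm, "_bland_altman.png")),
                     width = 900, height = 450)
      graphics::par(mfrow = c(1, 2))
      x <- report$per_subject
      cols <- switch(nm,
        tp_regional_vs_pressure = c("pwv_tp_regional", "pwv_pressure_regional"),
        ip_regional_vs_pressure = c("pwv_ip_regional", "pwv_pressure_regional"),
        ip_local_vs_pressure = c("pwv_ip_local", "pwv_pressure_local"),
        bh_cuff_vs_pressure = c("pwv_bh_cuff", "pwv_pressure_local"),
        bh_cath_vs_pressure = c("pwv_bh_cath", "pwv_pressure_local"))
      graphics::plot(x[[cols[2]]], x[[cols[1]]],
                     xlab = "reference PWV (m/s)", ylab = "test PWV (m/s)",
                     main = nm)
      graphics::abline(0, 1, lty = 2)
      m <- (x[[cols[1]]] + x[[cols[2]]]) / 2
      d <- x[[cols[1]]] - x[[cols[2]]]
      graphics::plot(m, d, xlab = "mean PWV (m/s)",
                     ylab = "difference (m/s)", main = "Bland-Altman")
      graphics::abline(h = c(a$mean_diff, a$loa_lo, a$loa_hi),
                       lty = c(1, 3, 3))
      grDevices::dev.off()
    }
  }
  invisible(dir)
}
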