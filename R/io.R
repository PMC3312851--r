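# Full-precision CSV writing (17 significant digits) so that an analysis is
# bit-reproducible across a write/read round trip; the default ~15-digit
# text conversion can flip discrete detector decisions (ties, thresholds).
.write_csv_precise <- function(df, path) {
  for (nm in names(df))
    if (is.double(df[[nm]]))
      df[[nm]] <- sub("^ +", "", sprintf("%.17g", df[[nm]]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write / read a waveform CSV with optional JSON sidecar
#'
#' The CSV has two columns `time_s,value` with a header. Multi-cycle
#' recordings add a JSON sidecar (same path with `.json` appended) holding
#' `r_wave_times_s`, `kind` and `site_position_m`.
#'
#' @param x A `sampled_waveform` or `multicycle_recording`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(x, path) {
  wf <- if (inherits(x, "multicycle_recording")) x$waveform else x
  stopifnot(inherits(wf, "sampled_waveform"))
  .write_csv_precise(data.frame(time_s = wf_times(wf), value = wf$values),
                     path)
  meta <- list(kind = wf$kind, rr_s = wf$rr_s,
               sample_interval_s = wf$sample_interval_s)
  if (inherits(x, "multicycle_recording")) {
    meta$r_wave_times_s <- x$r_wave_times_s
    meta$site_position_m <- x$site_position_m
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param path CSV file path (the sidecar is looked up automatically).
#' @return For `read_waveform_csv`: a `multicycle_recording` if the sidecar
#'   carries trigger times, otherwise a `sampled_waveform`.
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path))
    pwv_abort("config_error", sprintf("waveform CSV not found: %s", path))
  dat <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(dat)))
    pwv_abort("config_error", "waveform CSV must have columns time_s,value")
  side <- paste0(path, ".json")
  if (!file.exists(side))
    pwv_abort("config_error", sprintf("missing sidecar %s", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  wf <- sampled_waveform(dat$value,
                         sample_interval_s = meta$sample_interval_s,
                         start_time_s = dat$time_s[1L],
                         kind = meta$kind, rr_s = meta$rr_s)
  if (!is.null(meta$r_wave_times_s))
    return(multicycle_recording(wf, meta$r_wave_times_s,
                                meta$site_position_m %||% NA_real_))
  wf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read lumen contours as CSV
#'
#' Columns: `slice_id,phase_id,point_index,x_mm,y_mm`.
#'
#' @param contours A `lumen_contour` or list of them.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contours, path) {
  if (inherits(contours, "lumen_contour")) contours <- list(contours)
  rows <- do.call(rbind, lapply(contours, function(ct)
    data.frame(slice_id = ct$slice_id, phase_id = ct$phase_id,
               point_index = seq_len(nrow(ct$poly)),
               x_mm = ct$poly[, 1L], y_mm = ct$poly[, 2L])))
  .write_csv_precise(rows, path)
  invisible(path)
}

#' @rdname write_contour_csv
#' @param check_simple Verify polygons are simple on read.
#' @return For `read_contour_csv`: a list of `lumen_contour`, ordered by
#'   (slice_id, phase_id).
#' @export
read_contour_csv <- function(path, check_simple = TRUE) {
  dat <- utils::read.csv(path)
  need <- c("slice_id", "phase_id", "point_index", "x_mm", "y_mm")
  if (!all(need %in% names(dat)))
    pwv_abort("config_error", "contour CSV lacks required columns")
  keys <- unique(dat[, c("slice_id", "phase_id")])
  keys <- keys[order(keys$slice_id, keys$phase_id), , drop = FALSE]
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- dat[dat$slice_id == keys$slice_id[i] &
                 dat$phase_id == keys$phase_id[i], ]
    sub <- sub[order(sub$point_index), ]
    lumen_contour(sub$x_mm, sub$y_mm, slice_id = keys$slice_id[i],
                  phase_id = keys$phase_id[i], check_simple = check_simple)
  })
}

#' Write / read a velocity-map series as CSV frames + JSON header
#'
#' One CSV matrix per frame (`frame_001.csv`, ...) in `dir`, plus
#' `header.json` holding component, pixel spacing, phase times and venc.
#'
#' @param maps A `velocity_map_series`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_velocity_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "velocity_map_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in seq_along(maps$frames))
    utils::write.table(maps$frames[[p]],
                       file.path(dir, sprintf("frame_%03d.csv", p)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(component = maps$component,
                            pixel_spacing_mm = maps$pixel_spacing_mm,
                            phase_times_s = maps$phase_times_s,
                            venc_m_per_s = maps$venc_m_per_s,
                            rr_s = maps$rr_s),
                       file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' @rdname write_velocity_maps
#' @return For `read_velocity_maps`: a `velocity_map_series`.
#' @export
read_velocity_maps <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"),
                             simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.csv$",
                           full.names = TRUE))
  frames <- lapply(files, function(f)
    as.matrix(utils::read.csv(f, header = FALSE)))
  frames <- lapply(frames, unname)
  velocity_map_series(frames, component = hdr$component,
                      pixel_spacing_mm = hdr$pixel_spacing_mm,
                      phase_times_s = hdr$phase_times_s,
                      venc_m_per_s = hdr$venc_m_per_s, rr_s = hdr$rr_s)
}

#' Write a simulated cohort as a study directory
#'
#' Layout: `manifest.json` (subject ids, file map, site positions, blood
#' density, config hash and seed), `truth.csv`, and one directory per
#' subject holding the pullback waveform CSVs (with trigger sidecars), the
#' through-plane site curves, the chord curves (`chords.csv`, long format:
#' `chord_id,s_m,time_s,value`), the area series and the local CMR-grid
#' pressure curve, plus `subject.json` (cuff pulse pressure).
#'
#' @param cohort A `pwv_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pwv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  .write_csv_precise(cohort$truth, file.path(dir, "truth.csv"))
  for (i in seq_along(cohort$subjects)) {
    sd_ <- file.path(dir, sprintf("subject_%02d", i))
    dir.create(sd_, showWarnings = FALSE)
    subj <- cohort$subjects[[i]]
    for (k in seq_along(subj$pullback))
      write_waveform_csv(subj$pullback[[k]],
                         file.path(sd_, sprintf("pullback_%02d.csv", k)))
    write_waveform_csv(subj$tp_curves$site1, file.path(sd_, "tp_site1.csv"))
    write_waveform_csv(subj$tp_curves$site2, file.path(sd_, "tp_site2.csv"))
    pos <- attr(subj$chords, "arc_positions_m")
    long <- do.call(rbind, lapply(seq_along(subj$chords), function(j) {
      wf <- subj$chords[[j]]
      data.frame(chord_id = j, s_m = pos[j], time_s = wf_times(wf),
                 value = wf$values)
    }))
    .write_csv_precise(long, file.path(sd_, "chords.csv"))
    write_waveform_csv(subj$area, file.path(sd_, "area.csv"))
    write_waveform_csv(subj$pressure_local_cmr,
                       file.path(sd_, "pressure_cmr.csv"))
    jsonlite::write_json(list(pp_cuff_mmHg = subj$pp_cuff_mmHg,
                              D_effective_per_Pa = subj$D_effective_per_Pa),
                         file.path(sd_, "subject.json"),
                         auto_unbox = TRUE, digits = I(17))
  }
  manifest <- list(n_subjects = length(cohort$subjects),
                   subject_dirs = sprintf("subject_%02d",
                                          seq_along(cohort$subjects)),
                   site1_m = cfg$site1_m, site2_m = cfg$site2_m,
                   rho = cfg$rho, seed = cfg$seed,
                   config = unclass(cfg), config_hash = config_hash(cfg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' Read a study directory back into a cohort object
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `pwv_cohort`.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    pwv_abort("manifest_error", "manifest.json not found")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cfg <- manifest$config
  cfg$pullback_positions_m <- as.numeric(cfg$pullback_positions_m)
  config <- do.call(cohort_config, cfg[names(cfg) %in%
                                         names(formals(cohort_config))])
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  subjects <- lapply(seq_len(manifest$n_subjects), function(i) {
    sd_ <- file.path(dir, manifest$subject_dirs[i])
    if (!dir.exists(sd_))
      pwv_abort("manifest_error", sprintf("missing subject dir %s", sd_))
    pb_files <- sort(list.files(sd_, pattern = "^pullback_\\d+\\.csv$",
                                full.names = TRUE))
    pullback <- lapply(pb_files, read_waveform_csv)
    long <- utils::read.csv(file.path(sd_, "chords.csv"))
    ids <- sort(unique(long$chord_id))
    chords <- lapply(ids, function(j) {
      sub <- long[long$chord_id == j, ]
      sampled_waveform(sub$value,
                       sample_interval_s = mean(diff(sub$time_s)),
                       start_time_s = sub$time_s[1L], kind = "velocity",
                       rr_s = truth$rr_s[i])
    })
    attr(chords, "arc_positions_m") <-
      vapply(ids, function(j) long$s_m[long$chord_id == j][1L], numeric(1))
    meta <- jsonlite::read_json(file.path(sd_, "subject.json"),
                                simplifyVector = TRUE)
    tr <- subject_truth(truth$pwv_local_m_per_s[i],
                        truth$pwv_regional_m_per_s[i],
                        truth$pp_aortic_mmHg[i], truth$A_min_mm2[i],
                        truth$dbp_mmHg[i], truth$rr_s[i],
                        pp_cuff_mmHg = truth$pp_cuff_mmHg[i],
                        rho = config$rho)
    structure(list(
      pullback = pullback, chords = chords,
      tp_curves = list(site1 = read_waveform_csv(file.path(sd_, "tp_site1.csv")),
                       site2 = read_waveform_csv(file.path(sd_, "tp_site2.csv"))),
      area = read_waveform_csv(file.path(sd_, "area.csv")),
      pressure_local_cmr = read_waveform_csv(file.path(sd_, "pressure_cmr.csv")),
      pp_cuff_mmHg = meta$pp_cuff_mmHg,
      D_effective_per_Pa = meta$D_effective_per_Pa,
      truth = tr), class = "subject_dataset")
  })
  structure(list(config = config, truth = truth, subjects = subjects),
            class = "pwv_cohort")
}
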