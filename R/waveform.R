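#' Uniformly sampled physiologic waveform
#'
#' Container for a uniformly sampled signal over one or more cardiac cycles.
#' Times are relative to the R-wave for single-cycle waveforms.
#'
#' @param values Numeric vector of samples (non-empty, finite).
#' @param sample_interval_s Sampling interval in seconds (> 0).
#' @param start_time_s Time of the first sample, seconds relative to the
#'   R-wave (single cycles) or the recording origin (multi-cycle).
#' @param kind One of `"velocity"` (m/s), `"pressure"` (mmHg), `"area"` (mm^2).
#' @param rr_s Cardiac cycle duration in seconds (> 0).
#' @return An object of class `sampled_waveform`.
#' @export
sampled_waveform <- function(values, sample_interval_s, start_time_s = 0,
                             kind = c("velocity", "pressure", "area"),
                             rr_s) {
  kind <- match.arg(kind)
  if (length(values) < 1L || !all(is.finite(values)))
    pwv_abort("config_error", "waveform values must be non-empty and finite")
  if (!is.finite(sample_interval_s) || sample_interval_s <= 0)
    pwv_abort("config_error", "sample_interval_s must be > 0")
  if (!is.finite(rr_s) || rr_s <= 0)
    pwv_abort("config_error", "rr_s must be > 0")
  structure(list(values = as.numeric(values),
                 sample_interval_s = sample_interval_s,
                 start_time_s = start_time_s,
                 kind = kind,
                 rr_s = rr_s),
            class = "sampled_waveform")
}

#' Sample times of a waveform
#' @param wf A `sampled_waveform`.
#' @return Numeric vector of sample times in seconds.
#' @export
wf_times <- function(wf) {
  wf$start_time_s + (seq_along(wf$values) - 1L) * wf$sample_interval_s
}

#' @export
print.sampled_waveform <- function(x, ...) {
  cat(sprintf("<sampled_waveform> kind=%s n=%d dt=%.6gs rr=%.4gs start=%.4gs\n",
              x$kind, length(x$values), x$sample_interval_s, x$rr_s,
              x$start_time_s))
  invisible(x)
}

#' Multi-cycle recording with ECG trigger times
#'
#' A continuous waveform spanning one or more cardiac cycles together with
#' the R-wave trigger times used to segment it, and the arc-length position
#' of the measurement site along the vessel.
#'
#' @param waveform A `sampled_waveform` spanning >= 1 cycles.
#' @param r_wave_times_s Strictly increasing ECG trigger times, seconds.
#' @param site_position_m Arc-length position of the site from the
#'   aortic-valve end, metres.
#' @return An object of class `multicycle_recording`.
#' @export
multicycle_recording <- function(waveform, r_wave_times_s, site_position_m = NA_real_) {
  stopifnot(inherits(waveform, "sampled_waveform"))
  r <- as.numeric(r_wave_times_s)
  if (length(r) >= 2L && any(diff(r) <= 0))
    pwv_abort("segmentation_error", "r_wave_times_s must be strictly increasing")
  structure(list(waveform = waveform,
                 r_wave_times_s = r,
                 site_position_m = site_position_m),
            class = "multicycle_recording")
}

#' Segment a multi-cycle recording into per-cycle waveforms
#'
#' Splits the recording at consecutive R-wave triggers. Each returned cycle
#' has time zero at its trigger; concatenating the cycles reproduces the
#' original samples (between the first and last trigger) in order.
#'
#' @param recording A `multicycle_recording` with >= 2 triggers inside the
#'   recording span.
#' @return List of `sampled_waveform`, one per R-R interval.
#' @export
segment_cycles <- function(recording) {
  stopifnot(inherits(recording, "multicycle_recording"))
  wf <- recording$waveform
  trig <- recording$r_wave_times_s
  if (length(trig) < 2L)
    pwv_abort("segmentation_error", "need >= 2 R-wave triggers to segment")
  t <- wf_times(wf)
  span <- range(t)
  if (any(trig < span[1] - wf$sample_interval_s |
          trig > span[2] + wf$sample_interval_s))
    pwv_abort("segmentation_error", "trigger outside recording span")
  cycles <- vector("list", length(trig) - 1L)
  for (k in seq_len(length(trig) - 1L)) {
    idx <- which(t >= trig[k] & t < trig[k + 1L])
    if (length(idx) < 2L)
      pwv_abort("segmentation_error",
                sprintf("cycle %d contains fewer than 2 samples", k))
    cycles[[k]] <- sampled_waveform(
      values = wf$values[idx],
      sample_interval_s = wf$sample_interval_s,
      start_time_s = t[idx[1L]] - trig[k],
      kind = wf$kind,
      rr_s = trig[k + 1L] - trig[k])
  }
  cycles
}
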