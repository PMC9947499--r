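#' Preprocessing pipeline configuration
#'
#' Parameters of the two preprocessing pipelines: the ERP pipeline
#' (0.1-30 Hz band-pass, epoching, baseline correction) and the
#' resting-state classification pipeline (1 Hz high-pass, scalp channel
#' selection at projected radius <= 0.5, 45-55 Hz line-noise removal,
#' decimation to 125 Hz, common-average re-reference, 40 Hz low-pass).
#'
#' @param erp_highpass_hz,erp_lowpass_hz ERP band edges (Hz).
#' @param cls_highpass_hz,cls_lowpass_hz classification band edges (Hz).
#' @param line_band_hz two-element numeric, the line-noise stop band.
#' @param target_fs_hz decimation target for the classification pipeline.
#' @param scalp_radius_max scalp-channel cutoff on the projected radius
#'   (head circumference = 0.5 convention).
#' @param artifact_amplitude_uv,artifact_window_ms sliding-window
#'   peak-to-peak artifact rejection parameters.
#' @param filter_order Butterworth order for every filter stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(erp_highpass_hz = 0.1, erp_lowpass_hz = 30,
                            cls_highpass_hz = 1, cls_lowpass_hz = 40,
                            line_band_hz = c(45, 55), target_fs_hz = 125,
                            scalp_radius_max = 0.5,
                            artifact_amplitude_uv = 500, artifact_window_ms = 200,
                            filter_order = 4) {
  stopifnot(erp_highpass_hz > 0, erp_highpass_hz < erp_lowpass_hz,
            cls_highpass_hz > 0, cls_highpass_hz < cls_lowpass_hz,
            length(line_band_hz) == 2, line_band_hz[1] < line_band_hz[2],
            target_fs_hz > 0, filter_order >= 1)
  structure(list(erp_highpass_hz = erp_highpass_hz, erp_lowpass_hz = erp_lowpass_hz,
                 cls_highpass_hz = cls_highpass_hz, cls_lowpass_hz = cls_lowpass_hz,
                 line_band_hz = line_band_hz, target_fs_hz = target_fs_hz,
                 scalp_radius_max = scalp_radius_max,
                 artifact_amplitude_uv = artifact_amplitude_uv,
                 artifact_window_ms = artifact_window_ms,
                 filter_order = filter_order),
            class = "pipeline_config")
}

# zero-phase filtering with reflection padding; signal::filtfilt alone leaves
# visible edge transients for near-DC cutoffs
zp_filter <- function(x, filt, pad) {
  n <- length(x)
  pad <- max(1L, min(as.integer(pad), n - 1L))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(filt, xp)
  y[(pad + 1):(pad + n)]
}

apply_by_channel <- function(rec, fun) {
  out <- t(apply(rec$data, 1, fun))
  rownames(out) <- rec$channel_names
  rec$data <- out
  rec
}

#' Zero-phase band-pass filter
#'
#' Forward-backward Butterworth filtering (zero phase distortion), applied as
#' a high-pass/low-pass cascade. Either edge may be `NULL` for a one-sided
#' filter. Passband tones are preserved within 5%; a tone one octave past the
#' cutoff is attenuated by at least 20 dB at the default order.
#'
#' @param rec an [eeg_recording()].
#' @param low_hz high-pass edge (Hz) or `NULL`.
#' @param high_hz low-pass edge (Hz) or `NULL`.
#' @param order Butterworth order per section (default 4).
#' @return the filtered recording.
#' @export
bandpass_filter <- function(rec, low_hz, high_hz, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!is.null(low_hz)) {
    stop_if_not_scalar_number(low_hz, "low_hz", min = 0)
    if (low_hz >= nyq) stop("high-pass cutoff at or above Nyquist", call. = FALSE)
  }
  if (!is.null(high_hz)) {
    stop_if_not_scalar_number(high_hz, "high_hz", min = 0)
    if (high_hz >= nyq) stop("low-pass cutoff at or above Nyquist", call. = FALSE)
  }
  if (!is.null(low_hz) && !is.null(high_hz) && low_hz >= high_hz)
    stop("band edges inverted", call. = FALSE)
  if (!is.null(low_hz) && low_hz > 0) {
    hp <- butter_sos(order, low_hz / nyq, "high")
    rec <- apply_by_channel(rec, function(x) sos_filtfilt(x, hp, rec$fs))
  }
  if (!is.null(high_hz)) {
    lp <- butter_sos(order, high_hz / nyq, "low")
    rec <- apply_by_channel(rec, function(x) sos_filtfilt(x, lp, rec$fs))
  }
  rec
}

#' Remove line noise with a zero-phase band-stop filter
#'
#' Notches out the mains band (default 45-55 Hz). The contract is spectral:
#' power inside the band drops by at least 20 dB while broadband power
#' outside the band is essentially unchanged.
#'
#' @param rec an [eeg_recording()].
#' @param band_hz two-element numeric stop band (Hz).
#' @param order Butterworth order (default 4).
#' @return the filtered recording.
#' @export
remove_line_noise <- function(rec, band_hz = c(45, 55), order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(band_hz) != 2 || band_hz[1] >= band_hz[2])
    stop("`band_hz` must be an increasing (low, high) pair", call. = FALSE)
  nyq <- rec$fs / 2
  if (band_hz[1] <= 0 || band_hz[2] >= nyq)
    stop("stop band must lie strictly inside (0, fs/2)", call. = FALSE)
  bs <- signal::butter(order, band_hz / nyq, type = "stop")
  apply_by_channel(rec, function(x) zp_filter(x, bs, rec$fs))
}

#' Select scalp channels by projected radius
#'
#' Retains the channels whose montage radius is <= `radius_max` under the
#' head-circumference = 0.5 convention; face/cheek/neck electrodes beyond it
#' are dropped. On a 256-channel geodesic net this leaves 137 scalp channels.
#'
#' @param rec an [eeg_recording()] with a montage carrying radii.
#' @param radius_max radius cutoff (default 0.5).
#' @return the recording restricted to scalp channels (montage kept aligned).
#' @export
select_scalp_channels <- function(rec, radius_max = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$montage) || is.null(rec$montage$radius))
    stop("recording has no montage radii; cannot select scalp channels", call. = FALSE)
  keep <- which(rec$montage$radius <= radius_max)
  if (length(keep) == 0)
    stop("no channels at radius <= ", radius_max, call. = FALSE)
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$channel_names <- rec$channel_names[keep]
  rec$montage <- rec$montage[keep, , drop = FALSE]
  rownames(rec$montage) <- NULL
  rec
}

#' Downsample a recording by integer decimation
#'
#' Anti-alias low-pass filtering (zero-phase Butterworth at 80% of the new
#' Nyquist) followed by decimation. Only integer decimation factors are
#' supported; upsampling is out of scope.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target sampling rate, a divisor of `rec$fs`.
#' @param order anti-alias filter order.
#' @return the resampled recording (`fs` metadata updated).
#' @export
resample_recording <- function(rec, target_fs, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  stop_if_not_scalar_number(target_fs, "target_fs", min = .Machine$double.eps)
  if (target_fs > rec$fs) stop("upsampling is not supported", call. = FALSE)
  if (target_fs == rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("`target_fs` must divide the source sampling rate", call. = FALSE)
  q <- as.integer(round(q))
  aa <- butter_sos(order, 0.8 / q, "low")
  rec <- apply_by_channel(rec, function(x) sos_filtfilt(x, aa, rec$fs))
  rec$data <- rec$data[, seq(1, ncol(rec$data), by = q), drop = FALSE]
  rec$fs <- target_fs
  rec
}

#' Re-reference to the common average
#'
#' Subtracts the across-channel mean at every sample, so the channel mean is
#' zero everywhere. Idempotent.
#'
#' @param rec an [eeg_recording()] with at least 2 channels.
#' @return the re-referenced recording.
#' @export
rereference_to_mean <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2)
    stop("common-average reference needs at least 2 channels", call. = FALSE)
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Flag high-amplitude artifact segments
#'
#' Tiles the recording into consecutive windows and flags every window in
#' which any channel's peak-to-peak amplitude exceeds the threshold. The
#' sample mask is advisory: it is consumed by [epoch_recording()] to drop
#' contaminated trials. The signal itself is not modified.
#'
#' @param rec an [eeg_recording()].
#' @param amplitude_threshold_uv peak-to-peak threshold in microvolts.
#' @param window_ms window length in ms (> 0).
#' @return list with `recording` (unchanged), `mask` (logical per sample,
#'   `TRUE` = contaminated) and `windows` (data frame of flagged windows with
#'   `start_sample`, `end_sample`, `channel`). Errors if everything is masked.
#' @export
reject_artifact_segments <- function(rec, amplitude_threshold_uv, window_ms) {
  stopifnot(inherits(rec, "eeg_recording"))
  stop_if_not_scalar_number(amplitude_threshold_uv, "amplitude_threshold_uv", min = 0)
  if (!is.numeric(window_ms) || window_ms <= 0)
    stop("`window_ms` must be positive", call. = FALSE)
  ws <- max(1L, as.integer(round(window_ms * rec$fs / 1000)))
  n <- n_samples(rec)
  starts <- seq(1L, n, by = ws)
  mask <- rep(FALSE, n)
  flagged <- list()
  for (s in starts) {
    e <- min(s + ws - 1L, n)
    seg <- rec$data[, s:e, drop = FALSE]
    p2p <- apply(seg, 1, function(x) diff(range(x)))
    bad <- which(p2p > amplitude_threshold_uv)
    if (length(bad)) {
      mask[s:e] <- TRUE
      flagged[[length(flagged) + 1L]] <-
        data.frame(start_sample = s, end_sample = e,
                   channel = rec$channel_names[bad])
    }
  }
  if (all(mask))
    stop("every window exceeds the artifact threshold: recording unusable",
         call. = FALSE)
  windows <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(start_sample = integer(0), end_sample = integer(0),
               channel = character(0))
  list(recording = rec, mask = mask, windows = windows)
}

#' Segment a recording into stimulus-locked epochs
#'
#' Cuts a window (default -200..+1000 ms) around every schedule onset.
#' Onsets whose window is incomplete at the recording edges, or overlaps a
#' `TRUE` region of the artifact mask, are dropped. The time axis contains a
#' sample at t = 0 whenever `tmin_ms` is a whole number of sample periods.
#'
#' @param rec an [eeg_recording()].
#' @param schedule a `trial_schedule` (or data frame with `onset_ms` and
#'   `condition`).
#' @param tmin_ms,tmax_ms epoch window relative to onset (ms), `tmin_ms < 0
#'   <= tmax_ms`.
#' @param mask optional logical sample mask from [reject_artifact_segments()].
#' @return object of class `eeg_epochs`: list with `data` (trials x channels
#'   x time array), `fs`, `tmin_ms`, `tmax_ms`, `times_ms`, `channel_names`,
#'   `conditions`, `onsets_ms`, `baseline_window_ms` (`NULL` until
#'   [baseline_correct()]), plus `subject_id`/`cohort` copied from the
#'   recording.
#' @export
epoch_recording <- function(rec, schedule, tmin_ms = -200, tmax_ms = 1000,
                            mask = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(schedule) || nrow(schedule) == 0)
    stop("empty schedule: nothing to epoch", call. = FALSE)
  if (!(tmin_ms < 0 && tmax_ms >= 0))
    stop("epoch window must satisfy tmin_ms < 0 <= tmax_ms", call. = FALSE)
  len <- as.integer(round((tmax_ms - tmin_ms) * rec$fs / 1000))
  off0 <- as.integer(round(tmin_ms * rec$fs / 1000))
  onset_samp <- as.integer(round(schedule$onset_ms * rec$fs / 1000)) + 1L
  i0 <- onset_samp + off0
  ok <- i0 >= 1L & (i0 + len - 1L) <= n_samples(rec)
  if (!is.null(mask)) {
    ok <- ok & vapply(seq_along(i0), function(k) {
      if (!ok[k]) return(FALSE)
      !any(mask[i0[k]:(i0[k] + len - 1L)])
    }, logical(1))
  }
  if (!any(ok)) stop("no onsets with a complete, artifact-free window", call. = FALSE)
  keep <- which(ok)
  dat <- array(NA_real_, dim = c(length(keep), n_channels(rec), len))
  for (k in seq_along(keep)) {
    dat[k, , ] <- rec$data[, i0[keep[k]]:(i0[keep[k]] + len - 1L)]
  }
  new_epochs(dat, fs = rec$fs, tmin_ms = tmin_ms, tmax_ms = tmax_ms,
             channel_names = rec$channel_names,
             conditions = as.character(schedule$condition[keep]),
             onsets_ms = schedule$onset_ms[keep],
             subject_id = rec$subject_id, cohort = rec$cohort)
}

new_epochs <- function(data, fs, tmin_ms, tmax_ms, channel_names, conditions,
                       onsets_ms = NULL, subject_id = NA_character_,
                       cohort = NA_character_, baseline_window_ms = NULL) {
  stopifnot(length(dim(data)) == 3)
  len <- dim(data)[3]
  times_ms <- tmin_ms + (seq_len(len) - 1L) * 1000 / fs
  structure(list(data = data, fs = fs, tmin_ms = tmin_ms, tmax_ms = tmax_ms,
                 times_ms = times_ms, channel_names = channel_names,
                 conditions = conditions, onsets_ms = onsets_ms,
                 subject_id = subject_id, cohort = cohort,
                 baseline_window_ms = baseline_window_ms),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz (%g..%g ms)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              x$tmin_ms, x$tmax_ms))
  tb <- table(x$conditions)
  cat("  conditions:", paste(sprintf("%s(%d)", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus baseline
#' window (default [-200, 0) ms), so the baseline mean is exactly zero.
#'
#' @param epochs an `eeg_epochs` object.
#' @param window_ms two-element numeric baseline window (ms), interpreted as
#'   `[window_ms[1], window_ms[2])` and required to lie inside the epoch.
#' @return the corrected epochs, with `baseline_window_ms` recorded.
#' @export
baseline_correct <- function(epochs, window_ms = c(-200, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (length(window_ms) != 2 || window_ms[1] >= window_ms[2])
    stop("baseline window must be an increasing (start, end) pair", call. = FALSE)
  idx <- which(epochs$times_ms >= window_ms[1] & epochs$times_ms < window_ms[2])
  if (length(idx) == 0)
    stop("baseline window contains no samples", call. = FALSE)
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over the time axis
  epochs$baseline_window_ms <- window_ms
  epochs
}

#' ERP preprocessing pipeline
#'
#' The fixed ERP chain: 0.1-30 Hz zero-phase band-pass on the continuous
#' signal, windowed amplitude artifact rejection, epoching around schedule
#' onsets and pre-stimulus baseline correction.
#'
#' @param rec a raw [eeg_recording()].
#' @param schedule the paradigm `trial_schedule`.
#' @param config a [pipeline_config()].
#' @param tmin_ms,tmax_ms epoch window (ms).
#' @return baseline-corrected `eeg_epochs`.
#' @export
erp_preprocess <- function(rec, schedule, config = pipeline_config(),
                           tmin_ms = -200, tmax_ms = 1000) {
  rec <- bandpass_filter(rec, config$erp_highpass_hz, config$erp_lowpass_hz,
                         config$filter_order)
  rej <- reject_artifact_segments(rec, config$artifact_amplitude_uv,
                                  config$artifact_window_ms)
  ep <- epoch_recording(rej$recording, schedule, tmin_ms, tmax_ms, mask = rej$mask)
  baseline_correct(ep, c(tmin_ms, 0))
}

#' Resting-state classification preprocessing pipeline
#'
#' The fixed resting-state chain: 1 Hz high-pass, scalp channel selection
#' (projected radius <= 0.5), 45-55 Hz line-noise removal, an optional
#' pluggable cleaning hook, decimation to 125 Hz, common-average
#' re-reference and 40 Hz low-pass.
#'
#' @param rec a raw [eeg_recording()] with montage radii.
#' @param config a [pipeline_config()].
#' @param cleaning_hook optional `function(rec) rec` inserted where
#'   subspace-reconstruction / component-labelling cleaners would run.
#' @return the cleaned recording at `config$target_fs_hz`.
#' @export
classification_preprocess <- function(rec, config = pipeline_config(),
                                      cleaning_hook = NULL) {
  rec <- bandpass_filter(rec, config$cls_highpass_hz, NULL, config$filter_order)
  rec <- select_scalp_channels(rec, config$scalp_radius_max)
  rec <- remove_line_noise(rec, config$line_band_hz, config$filter_order)
  if (!is.null(cleaning_hook)) rec <- cleaning_hook(rec)
  rec <- resample_recording(rec, config$target_fs_hz, config$filter_order)
  rec <- rereference_to_mean(rec)
  bandpass_filter(rec, NULL, config$cls_lowpass_hz, config$filter_order)
}
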