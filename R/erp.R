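#' Grand-average ERP across subjects
#'
#' Computes subject-level trial averages first, then averages them across
#' subjects unweighted, so subjects with more surviving trials do not
#' dominate (trial-weighted averaging available by flag).
#'
#' @param epochs_list list of `eeg_epochs`, one per subject (each carrying
#'   `cohort` metadata).
#' @param cohort optional cohort label filter.
#' @param condition optional condition code filter (applied to trials).
#' @param weight_by_trials average trials pooled across subjects instead of
#'   the unweighted subject mean.
#' @return object of class `erp`: list with `waveform` (channels x time),
#'   `fs`, `tmin_ms`, `times_ms`, `channel_names`, `cohort`, `condition`,
#'   `n_subjects`, `n_trials_total`.
#' @export
grand_average <- function(epochs_list, cohort = NULL, condition = NULL,
                          weight_by_trials = FALSE) {
  stopifnot(is.list(epochs_list), length(epochs_list) >= 1)
  if (inherits(epochs_list, "eeg_epochs")) epochs_list <- list(epochs_list)
  if (!is.null(cohort))
    epochs_list <- Filter(function(e) identical(e$cohort, cohort), epochs_list)
  if (length(epochs_list) == 0)
    stop("no subjects match cohort ", cohort %||% "", call. = FALSE)
  sums <- NULL; n_subj <- 0L; n_trials <- 0L; w_sum <- 0L
  ref <- epochs_list[[1]]
  for (e in epochs_list) {
    stopifnot(inherits(e, "eeg_epochs"))
    sel <- if (is.null(condition)) seq_along(e$conditions) else
      which(e$conditions == condition)
    if (length(sel) == 0) next
    if (!isTRUE(all.equal(e$times_ms, ref$times_ms)) ||
        !identical(e$channel_names, ref$channel_names))
      stop("epochs are not on a common channel/time grid", call. = FALSE)
    m <- apply(e$data[sel, , , drop = FALSE], c(2, 3), mean)
    if (weight_by_trials) {
      sums <- if (is.null(sums)) m * length(sel) else sums + m * length(sel)
      w_sum <- w_sum + length(sel)
    } else {
      sums <- if (is.null(sums)) m else sums + m
    }
    n_subj <- n_subj + 1L
    n_trials <- n_trials + length(sel)
  }
  if (n_subj == 0)
    stop("no subjects with trials for condition ", condition %||% "", call. = FALSE)
  waveform <- if (weight_by_trials) sums / w_sum else sums / n_subj
  rownames(waveform) <- ref$channel_names
  structure(list(waveform = waveform, fs = ref$fs, tmin_ms = ref$tmin_ms,
                 times_ms = ref$times_ms, channel_names = ref$channel_names,
                 cohort = cohort %||% ref$cohort, condition = condition,
                 n_subjects = n_subj, n_trials_total = n_trials),
            class = "erp")
}

#' @export
print.erp <- function(x, ...) {
  cat(sprintf("<erp> %d channels x %d samples @ %g Hz; cohort %s, %d subjects, %d trials\n",
              nrow(x$waveform), ncol(x$waveform), x$fs,
              x$cohort %||% "?", x$n_subjects, x$n_trials_total))
  invisible(x)
}

#' Savitzky-Golay smoothing of a waveform
#'
#' Local least-squares polynomial smoothing for reporting and plots.
#' Polynomial inputs of degree <= `poly_order` pass through exactly; white
#' noise loses variance. A window of 1 is the identity. Correlation-based
#' electrode ranking is computed on unsmoothed averages; smoothing is a
#' presentation step.
#'
#' @param waveform numeric vector, or channels x time matrix (smoothed
#'   row-wise).
#' @param window_samples odd window length, >= `poly_order + 2` (or 1 for
#'   identity).
#' @param poly_order polynomial order (default 2).
#' @return smoothed waveform of the same shape.
#' @export
smooth_waveform <- function(waveform, window_samples = 11, poly_order = 2) {
  if (is.matrix(waveform)) {
    out <- t(apply(waveform, 1, smooth_waveform, window_samples, poly_order))
    dimnames(out) <- dimnames(waveform)
    return(out)
  }
  if (window_samples == 1) return(waveform)
  if (window_samples %% 2 == 0 || window_samples < poly_order + 2)
    stop("window must be odd and >= poly_order + 2", call. = FALSE)
  if (window_samples > length(waveform))
    stop("smoothing window longer than the waveform", call. = FALSE)
  as.numeric(signal::sgolayfilt(waveform, p = poly_order, n = window_samples))
}

#' Zero-lag cross-correlation between two grand averages
#'
#' Pearson correlation between the two ERPs' waveforms at one electrode,
#' computed at zero lag (the grand averages are time-locked to the same
#' stimulus). When `max_lag` > 0, the maximum-|r| lag within the scan range
#' is attached as attributes `best_lag` and `best_r`.
#'
#' @param erp_x,erp_y `erp` objects on the same time grid.
#' @param electrode electrode label present in both.
#' @param max_lag optional lag scan half-range in samples.
#' @return correlation coefficient in [-1, 1].
#' @export
cross_correlation <- function(erp_x, erp_y, electrode, max_lag = 0) {
  wx <- erp_channel(erp_x, electrode)
  wy <- erp_channel(erp_y, electrode)
  if (length(wx) != length(wy) ||
      !isTRUE(all.equal(erp_x$times_ms, erp_y$times_ms)))
    stop("ERPs are not on the same time grid", call. = FALSE)
  if (stats::sd(wx) == 0 || stats::sd(wy) == 0)
    stop("constant waveform at ", electrode, ": correlation undefined", call. = FALSE)
  r <- stats::cor(wx, wy)
  if (max_lag > 0) {
    lags <- -max_lag:max_lag
    rs <- vapply(lags, function(L) {
      if (L >= 0) stats::cor(wx[seq_len(length(wx) - L)], wy[(1 + L):length(wy)])
      else stats::cor(wx[(1 - L):length(wx)], wy[seq_len(length(wy) + L)])
    }, numeric(1))
    attr(r, "best_lag") <- lags[which.max(abs(rs))]
    attr(r, "best_r") <- rs[which.max(abs(rs))]
  }
  r
}

erp_channel <- function(erp, electrode) {
  stopifnot(inherits(erp, "erp"))
  i <- match(electrode, erp$channel_names)
  if (is.na(i)) stop("electrode ", electrode, " absent from ERP", call. = FALSE)
  erp$waveform[i, ]
}

#' Rank electrodes by smallest cross-cohort correlation
#'
#' For every electrode, computes the three pairwise zero-lag correlations
#' between the cohort grand averages (A-B, A-C, B-C) and ranks electrodes
#' ascending by the minimum of the three: the least-correlated electrodes
#' are where the cohorts' ERP shapes diverge most. Ties break by electrode
#' name.
#'
#' @param erp_A,erp_B,erp_C cohort grand averages on a common grid.
#' @param electrodes electrode set (default the 26 cognitive electrodes).
#' @param peak_window_ms window for the per-cohort peak amplitude column.
#' @return data frame of class `electrode_ranking`, ascending by `min_r`:
#'   `electrode`, `r_AB`, `r_AC`, `r_BC`, `min_r`, `peak_A`, `peak_B`,
#'   `peak_C`.
#' @export
rank_electrodes <- function(erp_A, erp_B, erp_C,
                            electrodes = cognitive_electrodes(),
                            peak_window_ms = NULL) {
  erps <- list(A = erp_A, B = erp_B, C = erp_C)
  for (e in electrodes) {
    present <- vapply(erps, function(x) e %in% x$channel_names, logical(1))
    if (!all(present))
      stop("electrode ", e, " absent from cohort ERP(s): ",
           paste(names(erps)[!present], collapse = ", "), call. = FALSE)
  }
  if (is.null(peak_window_ms)) peak_window_ms <- c(erp_A$tmin_ms, max(erp_A$times_ms))
  rows <- lapply(electrodes, function(e) {
    data.frame(electrode = e,
               r_AB = as.numeric(cross_correlation(erp_A, erp_B, e)),
               r_AC = as.numeric(cross_correlation(erp_A, erp_C, e)),
               r_BC = as.numeric(cross_correlation(erp_B, erp_C, e)),
               peak_A = peak_amplitude(erp_A, e, peak_window_ms)$amplitude_uv,
               peak_B = peak_amplitude(erp_B, e, peak_window_ms)$amplitude_uv,
               peak_C = peak_amplitude(erp_C, e, peak_window_ms)$amplitude_uv)
  })
  out <- do.call(rbind, rows)
  out$min_r <- pmin(out$r_AB, out$r_AC, out$r_BC)
  out <- out[order(out$min_r, out$electrode), ]
  rownames(out) <- NULL
  class(out) <- c("electrode_ranking", "data.frame")
  out
}

#' Signed peak amplitude of an ERP within a window
#'
#' Returns the signed extremum (largest |value|) and its latency within the
#' window. When two samples tie in |value|, the earlier latency is returned.
#'
#' @param erp an `erp` object.
#' @param electrode electrode label.
#' @param window_ms two-element numeric window (ms), inside the epoch span.
#' @return list with `amplitude_uv` (signed) and `latency_ms`.
#' @export
peak_amplitude <- function(erp, electrode, window_ms) {
  w <- erp_channel(erp, electrode)
  idx <- which(erp$times_ms >= window_ms[1] & erp$times_ms <= window_ms[2])
  if (length(idx) == 0) stop("empty peak window", call. = FALSE)
  k <- idx[which.max(abs(w[idx]))]  # which.max returns the first maximum: earlier tie wins
  list(amplitude_uv = w[k], latency_ms = erp$times_ms[k])
}
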