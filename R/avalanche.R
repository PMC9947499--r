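#' Avalanche detection configuration
#'
#' Parameters of the resting-state avalanche analysis: suprathreshold event
#' detection at +/- `threshold_sd` standard deviations, time binning at
#' `base_dt_ms * dt_multiplier` (defaults 8 ms x 3 = 24 ms, i.e. 3 samples at
#' 125 Hz), and a sweep over bin-width multipliers.
#'
#' @param threshold_sd detection threshold in per-channel SD units (default 2.7).
#' @param base_dt_ms base bin width in ms; 8 ms is one sample at 125 Hz.
#' @param dt_multiplier multiplier applied to `base_dt_ms` for feature
#'   extraction (default 3 -> 24 ms bins).
#' @param sweep_multipliers multipliers used by [sweep_bin_widths()].
#' @param edge_policy `"discard"` (default) drops cascades touching the first
#'   or last bin (their size is censored); `"keep"` retains them.
#' @param min_sizes minimum number of avalanche sizes required for an
#'   exponent fit.
#' @param x_min,x_max size-distribution fit range (`x_max = NULL` for an
#'   untruncated zeta fit).
#' @return list of class `detection_config`.
#' @export
detection_config <- function(threshold_sd = 2.7, base_dt_ms = 8, dt_multiplier = 3,
                             sweep_multipliers = 1:10,
                             edge_policy = c("discard", "keep"),
                             min_sizes = 100, x_min = 1, x_max = NULL) {
  stop_if_not_scalar_number(threshold_sd, "threshold_sd", min = .Machine$double.eps)
  stop_if_not_scalar_number(base_dt_ms, "base_dt_ms", min = .Machine$double.eps)
  stop_if_not_scalar_number(dt_multiplier, "dt_multiplier", min = 1)
  edge_policy <- match.arg(edge_policy)
  structure(list(threshold_sd = threshold_sd, base_dt_ms = base_dt_ms,
                 dt_multiplier = dt_multiplier, sweep_multipliers = sweep_multipliers,
                 edge_policy = edge_policy, min_sizes = min_sizes,
                 x_min = x_min, x_max = x_max),
            class = "detection_config")
}

#' Standardize each channel to zero mean and unit SD
#'
#' Per-channel z-scoring over the whole cleaned recording, using the
#' population SD convention (denominator n). Required before SD-threshold
#' event detection.
#'
#' @param rec an [eeg_recording()].
#' @return the z-scored recording (units become SD).
#' @export
zscore_channels <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  mu <- rowMeans(rec$data)
  centred <- rec$data - mu
  sdv <- sqrt(rowMeans(centred^2))
  bad <- which(sdv == 0)
  if (length(bad))
    stop("zero-variance channel(s): ", paste(rec$channel_names[bad], collapse = ", "),
         call. = FALSE)
  rec$data <- centred / sdv
  rec$units <- "SD"
  rec
}

#' Extract suprathreshold events per channel
#'
#' An event is one suprathreshold excursion: a maximal run of consecutive
#' samples with |z| > `threshold_sd`. Each excursion contributes exactly one
#' event, timed at the sample of its extremum (largest |z|), which prevents
#' long excursions from being double-counted.
#'
#' @param rec a z-scored [eeg_recording()] (see [zscore_channels()]).
#' @param threshold_sd detection threshold in SD units.
#' @return named list (one entry per channel) of strictly increasing event
#'   sample indices, with attributes `n_samples` and `fs`.
#' @export
extract_events <- function(rec, threshold_sd = 2.7) {
  stopifnot(inherits(rec, "eeg_recording"))
  stop_if_not_scalar_number(threshold_sd, "threshold_sd", min = .Machine$double.eps)
  ev <- lapply(seq_len(n_channels(rec)), function(ch) {
    z <- rec$data[ch, ]
    above <- abs(z) > threshold_sd
    if (!any(above)) return(integer(0))
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    vapply(runs, function(k) {
      i0 <- starts[k]; i1 <- ends[k]
      i0 + which.max(abs(z[i0:i1])) - 1L
    }, integer(1))
  })
  names(ev) <- rec$channel_names
  structure(ev, n_samples = n_samples(rec), fs = rec$fs)
}

#' Bin events into a channel x bin count raster
#'
#' Discretizes event sample indices into fixed-width time bins. The bin
#' width must be an integer number of samples; a trailing partial bin is
#' dropped (events falling in it are not counted).
#'
#' @param events output of [extract_events()].
#' @param fs sampling rate (defaults to the attribute carried by `events`).
#' @param bin_width_ms bin width in ms.
#' @return object of class `event_raster`: list with `counts`
#'   (channels x bins integer matrix), `bin_width_ms`, `samples_per_bin`,
#'   `n_samples_source`, `total_events`.
#' @export
bin_events <- function(events, fs = attr(events, "fs"), bin_width_ms) {
  n_src <- attr(events, "n_samples")
  if (is.null(n_src) || is.null(fs))
    stop("`events` must carry n_samples/fs attributes (see extract_events)", call. = FALSE)
  spb <- bin_width_ms * fs / 1000
  if (abs(spb - round(spb)) > 1e-6 || round(spb) < 1)
    stop(sprintf("bin width %g ms is not a whole number of samples at %g Hz",
                 bin_width_ms, fs), call. = FALSE)
  spb <- as.integer(round(spb))
  n_bins <- n_src %/% spb
  if (n_bins < 1) stop("recording shorter than one bin", call. = FALSE)
  counts <- t(vapply(events, function(idx) {
    b <- (idx - 1L) %/% spb + 1L
    tabulate(b[b <= n_bins], nbins = n_bins)
  }, integer(n_bins)))
  if (length(events) == 1L) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(names(events), NULL))
  structure(list(counts = counts, bin_width_ms = bin_width_ms,
                 samples_per_bin = spb, n_samples_source = n_src,
                 total_events = sum(counts)),
            class = "event_raster")
}

#' Segment a raster into avalanches
#'
#' An avalanche is a maximal run of consecutive bins whose total event count
#' (summed over channels) is >= 1, bounded by empty bins. Runs touching the
#' first or last bin of the raster are censored (their true extent is
#' unknown) and discarded under the default edge policy.
#'
#' @param raster an [bin_events()] raster.
#' @param edge_policy `"discard"` or `"keep"` for edge-touching runs.
#' @return list of class `avalanche_list`; each element has `start_bin`,
#'   `per_bin_counts` (bin totals within the run), `size`, `duration`.
#' @export
segment_avalanches <- function(raster, edge_policy = c("discard", "keep")) {
  stopifnot(inherits(raster, "event_raster"))
  edge_policy <- match.arg(edge_policy)
  totals <- colSums(raster$counts)
  n_bins <- length(totals)
  occ <- totals > 0
  out <- list()
  if (any(occ)) {
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (edge_policy == "discard" && (starts[k] == 1L || ends[k] == n_bins)) next
      counts <- totals[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- list(start_bin = starts[k],
                                      per_bin_counts = as.numeric(counts),
                                      size = sum(counts),
                                      duration = length(counts))
    }
  }
  structure(out, class = "avalanche_list", bin_width_ms = raster$bin_width_ms)
}

avalanche_sizes <- function(avalanches) vapply(avalanches, `[[`, numeric(1), "size")

# normalizing constant of the discrete power law s^-a on x_min..x_max
powerlaw_norm <- function(a, x_min, x_max = NULL) {
  if (!is.null(x_max) && is.finite(x_max)) {
    sum(seq(x_min, x_max)^(-a))
  } else if (x_min == 1) {
    pracma::zeta(a)
  } else {
    pracma::zeta(a) - sum(seq_len(x_min - 1)^(-a))
  }
}

powerlaw_loglik <- function(a, sizes, x_min, x_max = NULL) {
  -length(sizes) * log(powerlaw_norm(a, x_min, x_max)) - a * sum(log(sizes))
}

#' Fit the avalanche size-distribution exponent by maximum likelihood
#'
#' Discrete power-law fit P(s) proportional to s^alpha for s >= `x_min`,
#' maximising the zeta-normalised log-likelihood numerically. The returned
#' exponent uses the negative sign convention (a critical branching process
#' gives alpha close to -1.5).
#'
#' @param sizes avalanche sizes (positive integers); sizes below `x_min` are
#'   excluded before fitting.
#' @param x_min lower bound of the fit range (default 1).
#' @param x_max optional upper truncation (e.g. the channel count, to
#'   mitigate subsampling saturation); `NULL` for the untruncated zeta fit.
#' @param min_sizes minimum number of usable sizes (default 100; below this
#'   the MLE variance makes the exponent meaningless).
#' @return the fitted exponent (negative scalar).
#' @export
fit_size_exponent <- function(sizes, x_min = 1, x_max = NULL, min_sizes = 100) {
  sizes <- sizes[is.finite(sizes) & sizes >= x_min]
  if (length(sizes) < min_sizes)
    stop(sprintf("need at least %d sizes >= x_min for a fit (got %d)",
                 min_sizes, length(sizes)), call. = FALSE)
  if (length(unique(sizes)) == 1L)
    stop("all sizes equal: degenerate likelihood, no exponent is identified",
         call. = FALSE)
  opt <- stats::optimize(function(a) powerlaw_loglik(a, sizes, x_min, x_max),
                         interval = c(1 + 1e-6, 8), maximum = TRUE, tol = 1e-7)
  -opt$maximum
}

#' Estimate the branching parameter
#'
#' The branching parameter sigma is the expected number of next-bin events
#' per current-bin event. It is estimated as the mean over avalanches of the
#' ratio (second-bin total)/(first-bin total), with duration-1 avalanches
#' contributing 0. For cascades seeded with a single event this estimator's
#' expectation equals the offspring mean of the generating branching process.
#'
#' @param x an `avalanche_list` (from [segment_avalanches()]), a
#'   `cascade_set` (from [simulate_branching_cascades()]), or a plain list of
#'   per-bin count vectors.
#' @return estimated sigma (non-negative scalar).
#' @export
estimate_branching <- function(x) {
  counts <- if (inherits(x, "cascade_set")) {
    x$bin_totals
  } else if (inherits(x, "avalanche_list")) {
    lapply(x, `[[`, "per_bin_counts")
  } else if (is.list(x)) {
    x
  } else stop("unsupported input for estimate_branching", call. = FALSE)
  if (length(counts) == 0)
    stop("empty avalanche list: sigma is undefined", call. = FALSE)
  ratios <- vapply(counts, function(b) if (length(b) >= 2) b[2] / b[1] else 0,
                   numeric(1))
  mean(ratios)
}

#' Sweep avalanche features over bin widths
#'
#' Applies the full detection chain (threshold, bin, segment, fit) once per
#' bin-width multiplier, emulating the analysis that selects the working bin
#' width.
#'
#' @param rec a cleaned [eeg_recording()] (not yet z-scored).
#' @param config a [detection_config()].
#' @return data frame with one row per multiplier: `multiplier`,
#'   `bin_width_ms`, `alpha`, `sigma`, `n_avalanches`. `alpha` is `NA` when
#'   fewer than `min_sizes` avalanches survive.
#' @export
sweep_bin_widths <- function(rec, config = detection_config()) {
  stopifnot(inherits(config, "detection_config"))
  z <- zscore_channels(rec)
  ev <- extract_events(z, config$threshold_sd)
  rows <- lapply(config$sweep_multipliers, function(m) {
    raster <- bin_events(ev, bin_width_ms = config$base_dt_ms * m)
    av <- segment_avalanches(raster, config$edge_policy)
    sizes <- avalanche_sizes(av)
    alpha <- if (length(sizes[sizes >= config$x_min]) >= config$min_sizes &&
                 length(unique(sizes)) > 1L)
      fit_size_exponent(sizes, config$x_min, config$x_max, config$min_sizes)
    else NA_real_
    sigma <- if (length(av)) estimate_branching(av) else NA_real_
    data.frame(multiplier = m, bin_width_ms = config$base_dt_ms * m,
               alpha = alpha, sigma = sigma, n_avalanches = length(av))
  })
  do.call(rbind, rows)
}

#' Compute the avalanche feature vector of a recording
#'
#' Runs the full chain at the working bin width
#' (`base_dt_ms * dt_multiplier`, default 24 ms): per-channel z-scoring,
#' +/- `threshold_sd` event detection, binning, cascade segmentation,
#' exponent fit and branching estimate. The resulting (alpha, sigma) pair is
#' the classifier's feature vector.
#'
#' @param rec a cleaned [eeg_recording()].
#' @param config a [detection_config()].
#' @return object of class `avalanche_features`: list with `alpha`, `sigma`,
#'   `n_avalanches`, `bin_width_ms`, `n_recordings_aggregated`,
#'   `subject_id`, `cohort`.
#' @export
compute_features <- function(rec, config = detection_config()) {
  stopifnot(inherits(config, "detection_config"))
  z <- zscore_channels(rec)
  ev <- extract_events(z, config$threshold_sd)
  raster <- bin_events(ev, bin_width_ms = config$base_dt_ms * config$dt_multiplier)
  av <- segment_avalanches(raster, config$edge_policy)
  if (length(av) == 0)
    stop("no avalanches detected: feature vector undefined", call. = FALSE)
  sizes <- avalanche_sizes(av)
  alpha <- fit_size_exponent(sizes, config$x_min, config$x_max, config$min_sizes)
  sigma <- estimate_branching(av)
  structure(list(alpha = alpha, sigma = sigma, n_avalanches = length(av),
                 bin_width_ms = config$base_dt_ms * config$dt_multiplier,
                 n_recordings_aggregated = 1L,
                 subject_id = rec$subject_id, cohort = rec$cohort),
            class = "avalanche_features")
}

#' @export
print.avalanche_features <- function(x, ...) {
  cat(sprintf("<avalanche_features> alpha = %.4f, sigma = %.4f (%d avalanches, %g ms bins)\n",
              x$alpha, x$sigma, x$n_avalanches, x$bin_width_ms))
  invisible(x)
}

#' Aggregate per-recording avalanche features
#'
#' Mean and SD of alpha and sigma across recordings, the way cohort-level
#' values are reported (N = number of recordings entering the mean).
#'
#' @param features list of `avalanche_features`.
#' @return one-row data frame: `alpha_mean`, `alpha_sd`, `sigma_mean`,
#'   `sigma_sd`, `n_recordings`.
#' @export
aggregate_features <- function(features) {
  stopifnot(length(features) >= 1)
  al <- vapply(features, `[[`, numeric(1), "alpha")
  si <- vapply(features, `[[`, numeric(1), "sigma")
  data.frame(alpha_mean = mean(al), alpha_sd = stats::sd(al),
             sigma_mean = mean(si), sigma_sd = stats::sd(si),
             n_recordings = length(features))
}
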