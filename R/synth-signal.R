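#' Cohort specification for synthetic data
#'
#' Describes one sub-cohort of the three-group design (A: post-infection
#' with brain fog, B: post-infection without brain fog, C: never-infected
#' controls) in terms of the synthetic effect parameters: ERP amplitude
#' scaling and latency shift, resting-state branching parameter and size
#' exponent, and trial noise.
#'
#' @param label one of `"A"`, `"B"`, `"C"`.
#' @param n_subjects subjects in the cohort (>= 1).
#' @param erp_amplitude_scale unitless multiplier on the ERP template.
#' @param erp_latency_shift_ms template time shift in ms.
#' @param branching_parameter generative branching parameter sigma (>= 0).
#' @param size_exponent generative avalanche-size exponent (negative).
#' @param noise_sd_uv ERP trial noise SD in microvolts (>= 0).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(label, n_subjects = 40, erp_amplitude_scale = 1,
                        erp_latency_shift_ms = 0, branching_parameter = 1.1023,
                        size_exponent = -1.5336, noise_sd_uv = 10) {
  label <- match.arg(label, c("A", "B", "C"))
  stop_if_not_scalar_number(n_subjects, "n_subjects", min = 1)
  stop_if_not_scalar_number(branching_parameter, "branching_parameter", min = 0)
  stop_if_not_scalar_number(noise_sd_uv, "noise_sd_uv", min = 0)
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 erp_amplitude_scale = erp_amplitude_scale,
                 erp_latency_shift_ms = erp_latency_shift_ms,
                 branching_parameter = branching_parameter,
                 size_exponent = size_exponent, noise_sd_uv = noise_sd_uv),
            class = "cohort_spec")
}

#' Default three-cohort study design
#'
#' 40 subjects per sub-cohort (120 total). ERP amplitudes are ordered
#' B > A > C; controls (C) carry the resting-state reference values
#' (sigma = 1.1023, alpha = -1.5336) and the post-infection cohorts a
#' branching parameter reduced by 0.15.
#'
#' @param n_subjects subjects per cohort.
#' @param delta_sigma branching-parameter offset of cohorts A and B relative
#'   to C (default 0.15; set 0 for a null design).
#' @return named list of three [cohort_spec()]s.
#' @export
default_cohort_specs <- function(n_subjects = 40, delta_sigma = 0.15) {
  list(
    A = cohort_spec("A", n_subjects, erp_amplitude_scale = 1.0,
                    erp_latency_shift_ms = 12,
                    branching_parameter = 1.1023 - delta_sigma),
    B = cohort_spec("B", n_subjects, erp_amplitude_scale = 1.15,
                    erp_latency_shift_ms = 0,
                    branching_parameter = 1.1023 - delta_sigma),
    C = cohort_spec("C", n_subjects, erp_amplitude_scale = 0.85,
                    erp_latency_shift_ms = 0,
                    branching_parameter = 1.1023))
}

#' Resting-state background noise model
#'
#' The synthetic resting-state background: 1/f-shaped Gaussian noise
#' (z-scored to unit SD per channel), an optional mains tone, and an
#' optional 10 Hz "alpha" oscillation with per-channel random phase.
#' Eyes-closed resting EEG is alpha-dominated; the oscillation carries
#' signal variance without itself crossing the event-detection threshold,
#' which is what makes sparse suprathreshold events separable into cascades.
#'
#' @param pink shape the Gaussian background as 1/f (`FALSE` = white).
#' @param line_hz mains frequency (Hz) or `NULL` for none.
#' @param line_amp_sd mains tone amplitude in background-SD units.
#' @param osc_hz oscillation frequency (Hz) or `NULL` for none.
#' @param osc_amp_sd oscillation amplitude in background-SD units.
#' @return list of class `noise_model`.
#' @export
resting_noise_model <- function(pink = TRUE, line_hz = 50, line_amp_sd = 1,
                                osc_hz = 10, osc_amp_sd = 4) {
  structure(list(pink = pink, line_hz = line_hz, line_amp_sd = line_amp_sd,
                 osc_hz = osc_hz, osc_amp_sd = osc_amp_sd),
            class = "noise_model")
}

# one channel of unit-SD background noise
render_background <- function(n, fs, model) {
  x <- stats::rnorm(n)
  if (isTRUE(model$pink)) {
    f <- stats::fft(x)
    freqs <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
    gain <- c(0, 1 / sqrt(pmax(freqs[-1], 1)))  # 1/f power, floored at 1 Hz
    x <- Re(stats::fft(f * gain, inverse = TRUE)) / n
  }
  x <- (x - mean(x)) / stats::sd(x)
  tt <- (seq_len(n) - 1) / fs
  if (!is.null(model$osc_hz) && model$osc_amp_sd > 0)
    x <- x + model$osc_amp_sd * sin(2 * pi * model$osc_hz * tt + stats::runif(1, 0, 2 * pi))
  if (!is.null(model$line_hz) && model$line_amp_sd > 0)
    x <- x + model$line_amp_sd * sin(2 * pi * model$line_hz * tt + stats::runif(1, 0, 2 * pi))
  x
}

#' Render cascades into a resting-state recording
#'
#' Places the cascades of a [simulate_branching_cascades()] run (with
#' rasters) at random, non-adjacent bin positions in a continuous recording,
#' injecting each channel-bin occurrence as a brief biphasic deflection
#' whose peak magnitude exceeds `event_amplitude_sd` background SDs, with
#' random sign, on top of the background [resting_noise_model()]. Coincident
#' events on the same channel and bin merge into one deflection. Ground
#' truth (channel, bin, peak sample) is returned for recovery checks.
#'
#' @param cascades a `cascade_set` with rasters, or `NULL` to render pure
#'   background (in which case `truth` is `NULL`).
#' @param n_channels channel count when `cascades` is `NULL` and no montage
#'   is given.
#' @param fs sampling rate (Hz, default 250).
#' @param duration_s recording length in seconds; must be long enough to
#'   hold every cascade plus separating empty bins.
#' @param montage montage data frame; defaults to the scalp subset of
#'   [synthetic_geodesic_montage()] when the cascade channel count matches,
#'   otherwise a minimal synthetic ring.
#' @param noise_model a [resting_noise_model()].
#' @param event_amplitude_sd lower bound of the injected |amplitude| in units
#'   of the composed per-channel signal SD (default 4; actual draws are
#'   `event_amplitude_sd + U(1.5, 3.5)`, the margin absorbing downstream
#'   filtering attenuation), so deflections stay suprathreshold after
#'   whole-recording z-scoring.
#' @param bin_samples samples per cascade bin at `fs` (default 6 = 24 ms at
#'   250 Hz).
#' @param pulse_halfwidth event deflection half-width in samples.
#' @param noise_sd_uv scales the composed unit-SD signal to microvolts.
#' @param subject_id,cohort metadata attached to the recording.
#' @param seed integer seed or `NULL`.
#' @return list of class `resting_render`: `recording` (an
#'   [eeg_recording()]), `truth` (data frame: `cascade`, `channel`, `bin`,
#'   `peak_sample`, `count`), `bin_samples`, `start_bins`.
#' @export
render_resting_recording <- function(cascades, fs = 250, duration_s,
                                     montage = NULL, n_channels = NULL,
                                     noise_model = resting_noise_model(),
                                     event_amplitude_sd = 4, bin_samples = 6,
                                     pulse_halfwidth = 3, noise_sd_uv = 10,
                                     subject_id = NA_character_,
                                     cohort = NA_character_, seed = NULL) {
  if (is.null(cascades)) {
    nc <- n_channels %||% if (!is.null(montage)) nrow(montage) else
      stop("give `n_channels` or a montage when rendering pure background",
           call. = FALSE)
  } else {
    stopifnot(inherits(cascades, "cascade_set"))
    if (is.null(cascades$rasters))
      stop("cascade set has no rasters; rerun simulate_branching_cascades with make_rasters = TRUE",
           call. = FALSE)
    nc <- cascades$n_channels
  }
  n <- as.integer(round(duration_s * fs))
  n_bins <- n %/% bin_samples
  n_casc <- if (is.null(cascades)) 0L else length(cascades$rasters)
  if (n_casc > 0L) {
    need <- sum(cascades$durations) + n_casc + 1L
    if (need > n_bins)
      stop(sprintf("duration too short: %d bins needed (cascades + gaps), %d available",
                   need, n_bins), call. = FALSE)
  }
  if (is.null(montage)) {
    if (nc == 137) {
      m <- synthetic_geodesic_montage()
      montage <- m[m$radius <= 0.5, , drop = FALSE]
    } else {
      ang <- 2 * pi * (seq_len(nc) - 1) / nc
      montage <- data.frame(name = paste0("ch", seq_len(nc)),
                            x = 0.4 * cos(ang), y = 0.4 * sin(ang),
                            z = sqrt(pmax(0, 1 - 0.4^2)), radius = 0.4)
    }
  }
  montage <- validate_montage(montage)
  if (nrow(montage) != nc)
    stop("montage must have one row per cascade channel", call. = FALSE)

  with_seed(seed, {
    # random cascade placement with at least one empty bin between cascades
    if (n_casc > 0L) {
      extra <- n_bins - need
      gaps <- 1L + as.integer(stats::rmultinom(1, extra, rep(1, n_casc + 1L)))
      start_bins <- cumsum(gaps[seq_len(n_casc)] +
                             c(0L, cascades$durations[-n_casc])) + 1L
    } else {
      start_bins <- integer(0)
    }
    data <- matrix(0, nrow = nc, ncol = n)
    for (ch in seq_len(nc)) data[ch, ] <- render_background(n, fs, noise_model)
    # event amplitudes are in units of the composed per-channel signal SD, so
    # they stay suprathreshold after whole-recording z-scoring
    ch_sd <- sqrt(rowMeans(sweep(data, 1, rowMeans(data))^2))

    truth <- vector("list", n_casc)
    # peak near the bin centre, on an even offset so that integer decimation
    # (which keeps sample indices 1, 1+q, ...) retains the exact extremum
    peak_off <- (bin_samples %/% 2) - (bin_samples %/% 2) %% 2
    w <- pulse_halfwidth
    shape <- 1 - abs(seq(-w, w)) / (w + 1)
    for (k in seq_len(n_casc)) {
      ras <- cascades$rasters[[k]]
      hits <- which(ras > 0, arr.ind = TRUE)
      bin_global <- start_bins[k] + hits[, 2] - 1L
      peak <- (bin_global - 1L) * bin_samples + peak_off + 1L
      amp <- (event_amplitude_sd + stats::runif(nrow(hits), 1.5, 3.5)) *
        sample(c(-1, 1), nrow(hits), replace = TRUE) * ch_sd[hits[, 1]]
      for (j in seq_len(nrow(hits))) {
        idx <- (peak[j] - w):(peak[j] + w)
        keepi <- idx >= 1 & idx <= n
        data[hits[j, 1], idx[keepi]] <- data[hits[j, 1], idx[keepi]] +
          amp[j] * shape[keepi]
      }
      truth[[k]] <- data.frame(cascade = k, channel = montage$name[hits[, 1]],
                               bin = bin_global, peak_sample = peak,
                               count = ras[ras > 0])
    }
    rec <- eeg_recording(data * noise_sd_uv, fs = fs,
                         channel_names = montage$name, montage = montage,
                         subject_id = subject_id, cohort = cohort)
    structure(list(recording = rec, truth = do.call(rbind, truth),
                   bin_samples = bin_samples, start_bins = start_bins),
              class = "resting_render")
  })
}

#' Synthesize ERP trials from a template
#'
#' Builds `n_trials` epochs as
#' `amplitude_scale * template(t - latency_shift) + noise`, the generative
#' model behind the cohort ERP comparisons. With zero noise and unit scale
#' the trial average equals the template exactly; with noise, the average's
#' RMSE around the template shrinks as 1/sqrt(n_trials).
#'
#' @param template channels x time numeric matrix with attributes `fs` and
#'   `tmin_ms` (see [default_erp_template()]), or an object with the same
#'   shape.
#' @param n_trials number of trials.
#' @param amplitude_scale,latency_shift_ms,noise_sd_uv effect parameters;
#'   defaults taken from `cohort_spec` when given.
#' @param cohort_spec optional [cohort_spec()] supplying the effect
#'   parameters and cohort label.
#' @param conditions optional per-trial condition codes (recycled).
#' @param subject_id metadata.
#' @param seed integer seed or `NULL`.
#' @return an `eeg_epochs` object on the template's time grid.
#' @export
synthesize_erp_trials <- function(template, n_trials, amplitude_scale = 1,
                                  latency_shift_ms = 0, noise_sd_uv = 10,
                                  cohort_spec = NULL, conditions = "stim",
                                  subject_id = NA_character_, seed = NULL) {
  fs <- attr(template, "fs"); tmin_ms <- attr(template, "tmin_ms")
  if (is.null(fs) || is.null(tmin_ms))
    stop("template must carry `fs` and `tmin_ms` attributes (epoch grid mismatch)",
         call. = FALSE)
  if (!is.matrix(template)) template <- matrix(template, nrow = 1)
  cohort <- NA_character_
  if (!is.null(cohort_spec)) {
    stopifnot(inherits(cohort_spec, "cohort_spec"))
    amplitude_scale <- cohort_spec$erp_amplitude_scale
    latency_shift_ms <- cohort_spec$erp_latency_shift_ms
    noise_sd_uv <- cohort_spec$noise_sd_uv
    cohort <- cohort_spec$label
  }
  nchan <- nrow(template); len <- ncol(template)
  shift <- as.integer(round(latency_shift_ms * fs / 1000))
  shifted <- matrix(0, nchan, len)
  src <- seq_len(len) - shift
  okc <- src >= 1 & src <= len
  shifted[, okc] <- template[, src[okc], drop = FALSE]
  with_seed(seed, {
    dat <- array(NA_real_, dim = c(n_trials, nchan, len))
    for (i in seq_len(n_trials)) {
      dat[i, , ] <- amplitude_scale * shifted +
        matrix(stats::rnorm(nchan * len, sd = noise_sd_uv), nchan, len)
    }
    new_epochs(dat, fs = fs, tmin_ms = tmin_ms,
               tmax_ms = tmin_ms + (len - 1) * 1000 / fs,
               channel_names = rownames(template) %||% paste0("ch", seq_len(nchan)),
               conditions = rep_len(as.character(conditions), n_trials),
               subject_id = subject_id, cohort = cohort)
  })
}

#' Canonical ERP template for a paradigm
#'
#' A deterministic multichannel template built from Gaussian-windowed
#' components at the latencies classically associated with each paradigm
#' (face recognition: N170 and N400; digit span: N200 and P300; task
#' switching: N200 and a 350-400 ms positivity), spatially weighted across
#' the electrode set.
#'
#' @param paradigm one of `"face_recognition"`, `"digit_span"`,
#'   `"task_switching"`.
#' @param electrodes electrode labels (default the 26 cognitive electrodes).
#' @param fs sampling rate (Hz).
#' @param tmin_ms,tmax_ms template window (ms).
#' @return channels x time matrix (microvolts) with `fs` and `tmin_ms`
#'   attributes.
#' @export
default_erp_template <- function(paradigm = c("face_recognition", "digit_span",
                                              "task_switching"),
                                 electrodes = cognitive_electrodes(),
                                 fs = 250, tmin_ms = -200, tmax_ms = 1000) {
  paradigm <- match.arg(paradigm)
  len <- as.integer(round((tmax_ms - tmin_ms) * fs / 1000))
  t_ms <- tmin_ms + (seq_len(len) - 1) * 1000 / fs
  comp <- switch(paradigm,
    face_recognition = list(c(-4, 170, 25), c(-3, 400, 60)),
    digit_span       = list(c(-3, 200, 30), c(4, 320, 70)),
    task_switching   = list(c(-2, 210, 30), c(4, 375, 60)))
  wave <- rowSums(vapply(comp, function(p)
    p[1] * exp(-(t_ms - p[2])^2 / (2 * p[3]^2)), numeric(len)))
  nchan <- length(electrodes)
  spatial <- exp(-((seq_len(nchan) - (nchan + 1) / 2)^2) / (2 * (nchan / 3)^2))
  out <- outer(spatial, wave)
  rownames(out) <- electrodes
  attr(out, "fs") <- fs
  attr(out, "tmin_ms") <- tmin_ms
  out
}

#' Generate a full labelled cohort dataset
#'
#' One resting-state recording (cascades rendered into signal) and three
#' paradigms' ERP epochs per subject, for every cohort in `specs`.
#' Per-subject seeds are derived deterministically from the master seed, so
#' distinct subjects get distinct signals and the whole dataset is a pure
#' function of `(specs, sizes, seed)`.
#'
#' @param specs list of [cohort_spec()]s (default [default_cohort_specs()]).
#' @param seed master seed.
#' @param n_channels resting-state channel count.
#' @param resting_duration_s resting recording length per subject (s).
#' @param n_cascades cascades injected per resting recording.
#' @param trials_per_paradigm named or unnamed count(s) of ERP trials per
#'   paradigm.
#' @param max_duration cascade duration cap (bins).
#' @return list of class `cohort_dataset`: `subjects` (data frame of
#'   `subject_id`, `cohort`), `resting` (named list of `resting_render`),
#'   `epochs` (named list: per subject, a named list of `eeg_epochs` per
#'   paradigm), `specs`, `seed`.
#' @export
build_cohort_dataset <- function(specs = default_cohort_specs(), seed = 1,
                                 n_channels = 32, resting_duration_s = 60,
                                 n_cascades = 150, trials_per_paradigm = 30,
                                 max_duration = 20) {
  if (length(specs) == 0) stop("empty cohort list", call. = FALSE)
  stopifnot(all(vapply(specs, inherits, logical(1), "cohort_spec")))
  paradigms <- c("face_recognition", "digit_span", "task_switching")
  trials <- rep_len(trials_per_paradigm, length(paradigms))
  subjects <- do.call(rbind, lapply(specs, function(sp)
    data.frame(subject_id = sprintf("%s%02d", sp$label, seq_len(sp$n_subjects)),
               cohort = sp$label)))
  rownames(subjects) <- NULL
  resting <- list(); epochs <- list()
  for (sp in specs) {
    for (i in seq_len(sp$n_subjects)) {
      sid <- sprintf("%s%02d", sp$label, i)
      cs <- simulate_branching_cascades(
        n_channels, sp$branching_parameter, n_cascades,
        seed = derive_seed(seed, paste0("cascades-", sid)),
        max_duration = max_duration)
      resting[[sid]] <- render_resting_recording(
        cs, duration_s = resting_duration_s,
        noise_sd_uv = sp$noise_sd_uv, subject_id = sid, cohort = sp$label,
        seed = derive_seed(seed, paste0("render-", sid)))
      epochs[[sid]] <- lapply(stats::setNames(seq_along(paradigms), paradigms),
        function(p) {
          tpl <- default_erp_template(paradigms[p])
          synthesize_erp_trials(tpl, trials[p], cohort_spec = sp,
                                subject_id = sid,
                                seed = derive_seed(seed, paste0(paradigms[p], "-", sid)))
        })
    }
  }
  structure(list(subjects = subjects, resting = resting, epochs = epochs,
                 specs = specs, seed = seed),
            class = "cohort_dataset")
}

#' Simulate cohort avalanche features directly from cascades
#'
#' The feature-level generator used for classifier calibration and power
#' studies: per subject, draws cascades at the cohort's branching parameter
#' and computes the (alpha, sigma) feature vector from them, bypassing
#' signal rendering and detection. Much faster than [build_cohort_dataset()]
#' while preserving the feature distributions the classifier sees.
#'
#' @param specs list of [cohort_spec()]s.
#' @param n_cascades cascades per subject.
#' @param max_duration cascade duration cap (bins).
#' @param seed master seed.
#' @return data frame with `subject_id`, `cohort`, `alpha`, `sigma`,
#'   `n_avalanches`.
#' @export
simulate_cohort_features <- function(specs = default_cohort_specs(),
                                     n_cascades = 1500, max_duration = 30,
                                     seed = 1) {
  if (length(specs) == 0) stop("empty cohort list", call. = FALSE)
  rows <- list()
  for (sp in specs) {
    for (i in seq_len(sp$n_subjects)) {
      sid <- sprintf("%s%02d", sp$label, i)
      cs <- simulate_branching_cascades(
        1, sp$branching_parameter, n_cascades,
        seed = derive_seed(seed, paste0("feat-", sid)),
        max_duration = max_duration, make_rasters = FALSE)
      rows[[sid]] <- data.frame(
        subject_id = sid, cohort = sp$label,
        alpha = fit_size_exponent(cs$sizes),
        sigma = estimate_branching(cs),
        n_avalanches = length(cs$sizes))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
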