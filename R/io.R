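#' Write / read a recording in the matrix + header dialect
#'
#' A recording is stored as two files sharing a stem: `<stem>.csv`, the
#' samples x channels matrix with channel names as the header row, and
#' `<stem>.json`, the sidecar header (sampling rate, units, subject/cohort
#' metadata and the montage). The roundtrip is exact up to the decimal
#' representation written to the CSV (15 significant digits, relative error
#' below 1e-12).
#'
#' @param rec an [eeg_recording()].
#' @param stem file path without extension (or a `.csv` path; the sidecar
#'   replaces the extension with `.json`).
#' @return `write_recording` invisibly returns the two paths;
#'   `read_recording` returns the recording.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  stem <- sub("\\.(csv|json)$", "", stem)
  csv <- paste0(stem, ".csv"); json <- paste0(stem, ".json")
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_names
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   csv, row.names = FALSE, quote = FALSE)
  header <- list(fs = rec$fs, units = rec$units,
                 channel_names = rec$channel_names,
                 subject_id = rec$subject_id, cohort = rec$cohort,
                 montage = rec$montage)
  jsonlite::write_json(header, json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = csv, json = json))
}

#' @rdname write_recording
#' @param path stem, `.csv` or `.json` path of a stored recording.
#' @export
read_recording <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("", "csv", "json"))
    stop("unknown recording extension `.", ext,
         "`: expected a .csv/.json pair", call. = FALSE)
  stem <- sub("\\.(csv|json)$", "", path)
  csv <- paste0(stem, ".csv"); json <- paste0(stem, ".json")
  if (!file.exists(csv)) stop("recording matrix not found: ", csv, call. = FALSE)
  if (!file.exists(json))
    stop("malformed recording: missing header sidecar ", json, call. = FALSE)
  header <- tryCatch(jsonlite::read_json(json, simplifyVector = TRUE),
                     error = function(e)
                       stop("malformed recording header: ", conditionMessage(e),
                            call. = FALSE))
  if (is.null(header$fs) || !is.numeric(header$fs) || header$fs <= 0)
    stop("recording header has invalid sampling rate (fs <= 0 or missing)",
         call. = FALSE)
  mat <- tryCatch(as.matrix(utils::read.csv(csv, check.names = FALSE)),
                  error = function(e)
                    stop("malformed recording matrix: ", conditionMessage(e),
                         call. = FALSE))
  if (length(mat) == 0) stop("malformed recording: empty matrix file", call. = FALSE)
  if (ncol(mat) != length(header$channel_names))
    stop(sprintf("channel count mismatch: header lists %d channels, matrix has %d columns",
                 length(header$channel_names), ncol(mat)), call. = FALSE)
  montage <- header$montage
  if (!is.null(montage) && length(montage)) montage <- as.data.frame(montage)
  else montage <- NULL
  eeg_recording(t(mat), fs = as.numeric(header$fs),
                channel_names = as.character(header$channel_names),
                montage = montage,
                subject_id = header$subject_id %||% NA_character_,
                cohort = header$cohort %||% NA_character_,
                units = header$units %||% "uV")
}

#' Read / write an electrode montage CSV
#'
#' A montage is a CSV with columns `name`, `x`, `y`, `z`, `radius` (the
#' projected radius under the head-circumference = 0.5 convention). A
#' bundled synthetic 256-channel geodesic montage ships with the package
#' (`system.file("extdata", "hydrocel256_synthetic_montage.csv", package =
#' "eegavalanche")`).
#'
#' @param path CSV file path.
#' @return data frame with the five montage columns.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path, call. = FALSE)
  validate_montage(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_montage
#' @param montage a montage data frame.
#' @export
write_montage <- function(montage, path) {
  utils::write.csv(validate_montage(montage), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a trial schedule CSV
#'
#' Columns `onset_ms`, `condition`, `payload` plus any paradigm-specific
#' extras; the paradigm name travels in a `paradigm` column.
#' @param schedule a `trial_schedule`.
#' @param path CSV file path.
#' @export
write_schedule <- function(schedule, path) {
  df <- as.data.frame(schedule)
  df$paradigm <- attr(schedule, "paradigm")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  paradigm <- unique(df$paradigm) %||% "unknown"
  df$paradigm <- NULL
  structure(df, paradigm = paradigm, class = c("trial_schedule", "data.frame"))
}

#' Full-run configuration
#'
#' Gathers every parameter of an end-to-end run: the master seed, cohort
#' specifications, pipeline/detection/classification settings, the demo
#' problem sizes and the output directory. Serialises losslessly to JSON.
#'
#' @param seed master seed; every stochastic stage draws a named derived
#'   stream from it.
#' @param cohort_specs list of [cohort_spec()]s.
#' @param n_subjects subjects per cohort (applied over `cohort_specs`).
#' @param erp_trials ERP trials per subject and paradigm.
#' @param erp_noise_sd_uv ERP trial noise (microvolts).
#' @param n_cascades cascades per subject for the feature generator.
#' @param test_fraction,n_folds,shrinkage classifier settings.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, cohort_specs = default_cohort_specs(),
                       n_subjects = 8, erp_trials = 30, erp_noise_sd_uv = 8,
                       n_cascades = 1500, test_fraction = 0.3, n_folds = 6,
                       shrinkage = 0.1, out_dir = tempfile("eegavalanche_run_")) {
  if (length(cohort_specs) == 0) stop("empty cohort list", call. = FALSE)
  for (i in seq_along(cohort_specs)) cohort_specs[[i]]$n_subjects <- as.integer(n_subjects)
  structure(list(seed = seed, cohort_specs = cohort_specs,
                 n_subjects = n_subjects, erp_trials = erp_trials,
                 erp_noise_sd_uv = erp_noise_sd_uv, n_cascades = n_cascades,
                 test_fraction = test_fraction, n_folds = n_folds,
                 shrinkage = shrinkage, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates one reproducible end-to-end run: (1) synthesize per-subject
#' ERP epochs for the three paradigms and every cohort, compute cohort grand
#' averages and the cross-correlation electrode ranking; (2) simulate
#' per-subject avalanche features; (3) run the five LDA comparison tasks;
#' (4) write every table as CSV plus a JSON manifest of config, file
#' checksums and versions. Re-running an identical config reproduces
#' identical outputs (and checksums).
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly; files are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paradigms <- c("face_recognition", "digit_span", "task_switching")
  message("stage erp: ", config$n_subjects, " subjects/cohort x ",
          config$erp_trials, " trials x ", length(paradigms), " paradigms")

  ranking_paths <- character(0)
  for (par in paradigms) {
    tpl <- default_erp_template(par)
    erps <- lapply(config$cohort_specs, function(sp) {
      subj <- lapply(seq_len(sp$n_subjects), function(i) {
        sp2 <- sp; sp2$noise_sd_uv <- config$erp_noise_sd_uv
        synthesize_erp_trials(tpl, config$erp_trials, cohort_spec = sp2,
                              subject_id = sprintf("%s%02d", sp$label, i),
                              seed = derive_seed(config$seed,
                                                 paste0("erp-", par, "-", sp$label, i)))
      })
      grand_average(subj, cohort = sp$label)
    })
    ranking <- rank_electrodes(erps$A, erps$B, erps$C)
    ranking$paradigm <- par
    path <- file.path(out, paste0("erp_ranking_", par, ".csv"))
    utils::write.csv(ranking, path, row.names = FALSE)
    ranking_paths <- c(ranking_paths, path)
    # per-electrode waveforms of the 3 least-correlated electrodes
    top <- ranking$electrode[seq_len(min(3, nrow(ranking)))]
    wf <- data.frame(time_ms = erps$A$times_ms)
    for (e in top) {
      wf[[paste0(e, "_A")]] <- erp_channel(erps$A, e)
      wf[[paste0(e, "_B")]] <- erp_channel(erps$B, e)
      wf[[paste0(e, "_C")]] <- erp_channel(erps$C, e)
    }
    wpath <- file.path(out, paste0("erp_waveforms_", par, ".csv"))
    utils::write.csv(wf, wpath, row.names = FALSE)
    ranking_paths <- c(ranking_paths, wpath)
  }

  message("stage features: ", config$n_cascades, " cascades/subject")
  features <- simulate_cohort_features(config$cohort_specs,
                                       n_cascades = config$n_cascades,
                                       seed = derive_seed(config$seed, "features"))
  fpath <- file.path(out, "features.csv")
  utils::write.csv(features, fpath, row.names = FALSE)

  message("stage classify: 5 comparison tasks, ", config$n_folds, "-fold CV")
  report <- run_comparisons(features, test_fraction = config$test_fraction,
                            n_folds = config$n_folds, shrinkage = config$shrinkage,
                            seed = derive_seed(config$seed, "classify"))
  cvpath <- file.path(out, "cv_report.csv")
  tpath <- file.path(out, "test_report.csv")
  utils::write.csv(report$cv, cvpath, row.names = FALSE)
  utils::write.csv(report$test, tpath, row.names = FALSE)
  cpath <- file.path(out, "confusion_counts.json")
  jsonlite::write_json(lapply(report$counts, as.list), cpath, auto_unbox = TRUE)

  files <- c(ranking_paths, fpath, cvpath, tpath, cpath)
  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    config = jsonlite::fromJSON(cfg_json),
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files))),
    package_version = as.character(utils::packageVersion("eegavalanche")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
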