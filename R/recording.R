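#' Construct a multichannel EEG recording
#'
#' The central container of the package: a channels-by-samples numeric matrix
#' in microvolts plus sampling rate, channel names, an optional electrode
#' montage and subject/cohort metadata.
#'
#' @param data numeric matrix, channels x samples, microvolts. Row names (if
#'   present) are taken as channel names.
#' @param fs sampling rate in Hz, > 0.
#' @param channel_names character vector, one per row of `data`.
#' @param montage optional data frame with columns `name`, `x`, `y`, `z`,
#'   `radius` covering every channel (see [read_montage()]).
#' @param subject_id,cohort optional metadata strings.
#' @param units signal units; only `"uV"` is used by the pipelines.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL, montage = NULL,
                          subject_id = NA_character_, cohort = NA_character_,
                          units = "uV") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  stop_if_not_scalar_number(fs, "fs", min = .Machine$double.eps)
  if (is.null(channel_names)) {
    channel_names <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data))
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  if (anyDuplicated(channel_names))
    stop("duplicate channel names", call. = FALSE)
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples", call. = FALSE)
  if (!is.null(montage)) {
    montage <- validate_montage(montage)
    missing <- setdiff(channel_names, montage$name)
    if (length(missing))
      stop("montage does not cover channels: ", paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
    montage <- montage[match(channel_names, montage$name), , drop = FALSE]
    rownames(montage) <- NULL
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names, montage = montage,
         subject_id = subject_id, cohort = cohort, units = units),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "")
  if (!is.na(x$cohort)) cat(" cohort:", x$cohort)
  if (!is.na(x$subject_id) || !is.na(x$cohort)) cat("\n")
  if (!is.null(x$montage)) cat("  montage:", nrow(x$montage), "electrode positions\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

validate_montage <- function(montage) {
  montage <- as.data.frame(montage)
  need <- c("name", "x", "y", "z", "radius")
  missing <- setdiff(need, names(montage))
  if ("radius" %in% missing)
    stop("montage is missing the `radius` column", call. = FALSE)
  if (length(missing))
    stop("montage is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(montage$name))
    stop("montage has duplicate channel names", call. = FALSE)
  if (!all(is.finite(montage$radius)))
    stop("montage radii must all be finite", call. = FALSE)
  montage$name <- as.character(montage$name)
  montage
}

#' The 26 cognitive electrodes of the 256-channel geodesic net
#'
#' Posterior channels designated for cognitive ERP observation on dense-array
#' geodesic sensor nets.
#' @return character vector of 26 electrode labels.
#' @export
cognitive_electrodes <- function() {
  c("E98", "E99", "E100", "E101", "E108", "E109", "E110", "E116", "E117",
    "E118", "E119", "E124", "E125", "E126", "E127", "E128", "E129", "E137",
    "E138", "E139", "E140", "E141", "E149", "E150", "E151", "E152")
}

#' Synthetic 256-channel geodesic montage
#'
#' A deterministic stand-in for a dense-array geodesic sensor net, built from
#' a Fibonacci lattice over a spherical cap extending below the head
#' circumference (covering cheek/neck positions like real dense nets). The
#' 2-D projected radius uses the convention head-circumference = 0.5 and is
#' calibrated so that exactly `scalp_count` channels have radius <= 0.5. The
#' 26 cognitive electrode labels are assigned to posterior scalp positions.
#' Coordinates are synthetic: they emulate the layout's structure (counts,
#' radius convention, posterior cognitive subset), not true electrode
#' positions.
#'
#' @param n total electrode count.
#' @param scalp_count electrodes that must fall at radius <= 0.5.
#' @return data frame with columns `name`, `x`, `y`, `z`, `radius`.
#' @export
synthetic_geodesic_montage <- function(n = 256, scalp_count = 137) {
  stopifnot(n >= scalp_count, scalp_count >= length(cognitive_electrodes()))
  # uniform-area cap: solid-angle fraction puts ~scalp_count points above the equator
  cos_theta_max <- 1 - (n / scalp_count)
  u <- (seq_len(n) - 0.5) / n
  cos_theta <- 1 - u * (1 - cos_theta_max)
  theta <- acos(pmin(1, pmax(-1, cos_theta)))
  golden <- pi * (3 - sqrt(5))
  phi <- (seq_len(n) * golden) %% (2 * pi)
  x <- sin(theta) * cos(phi)
  y <- sin(theta) * sin(phi)
  z <- cos_theta
  raw_r <- theta / pi  # equator (head circumference) at 0.5 before calibration
  ord <- order(raw_r)
  r_sorted <- raw_r[ord]
  # calibrate so exactly scalp_count channels have radius <= 0.5
  cal <- 0.5 / ((r_sorted[scalp_count] + r_sorted[scalp_count + 1]) / 2)
  radius <- raw_r * cal

  scalp <- which(radius <= 0.5)
  cog <- cognitive_electrodes()
  # cognitive labels -> most posterior scalp positions (smallest y), ordered by x
  posterior <- scalp[order(y[scalp])][seq_along(cog)]
  posterior <- posterior[order(x[posterior])]
  name <- character(n)
  name[posterior] <- cog
  rest_labels <- setdiff(paste0("E", seq_len(n)), cog)
  name[name == ""] <- rest_labels
  data.frame(name = name, x = x, y = y, z = z, radius = radius,
             stringsAsFactors = FALSE)
}
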