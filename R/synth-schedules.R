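#' Paradigm trial schedules
#'
#' Generators for the three cognitive paradigms' trial schedules: digit span,
#' task switching and face recognition. A schedule is a data frame with one
#' row per trial and columns `trial`, `condition`, `payload`, `onset_ms`
#' (strictly increasing onsets), carrying the paradigm name as an attribute.
#'
#' @name trial_schedules
NULL

new_trial_schedule <- function(df, paradigm) {
  df$trial <- seq_len(nrow(df))
  df <- df[, c("trial", setdiff(names(df), "trial"))]
  stopifnot(all(diff(df$onset_ms) > 0))
  structure(df, paradigm = paradigm, class = c("trial_schedule", "data.frame"))
}

#' Digit-span trial schedule
#'
#' Auditory digit sequences of increasing length. The default per-length
#' counts follow the study design: 10 three-digit and 10 four-digit
#' sequences, 5 each of lengths 5-8, 9 nine-digit and 15 ten-digit
#' sequences, 64 trials in total, ordered by increasing length. Within one
#' length block every sequence is distinct.
#'
#' @param counts named integer vector: names are sequence lengths, values the
#'   number of sequences of that length.
#' @param digits the digit alphabet (default 1..10).
#' @param seed integer seed for sequence sampling, or `NULL`.
#' @return a `trial_schedule`; `payload` holds the dash-separated sequence,
#'   `condition` the length code (e.g. `"len3"`).
#' @export
make_digit_span_schedule <- function(counts = c(`3` = 10, `4` = 10, `5` = 5, `6` = 5,
                                                `7` = 5, `8` = 5, `9` = 9, `10` = 15),
                                     digits = 1:10, seed = NULL) {
  if (length(counts) == 0 || any(counts < 0) || sum(counts) < 1)
    stop("`counts` must request at least one sequence", call. = FALSE)
  lens <- as.integer(names(counts))
  if (anyNA(lens) || any(lens < 1))
    stop("names of `counts` must be positive sequence lengths", call. = FALSE)
  n_alpha <- length(digits)
  possible <- n_alpha^lens
  if (any(counts > possible))
    stop(sprintf("cannot draw %d distinct sequences of length %d from %d digits",
                 max(counts[counts > possible]), lens[which(counts > possible)[1]], n_alpha),
         call. = FALSE)
  ord <- order(lens)
  lens <- lens[ord]; counts <- counts[ord]
  with_seed(seed, {
    rows <- lapply(seq_along(lens), function(i) {
      len <- lens[i]; k <- counts[i]
      if (k == 0) return(NULL)
      seqs <- character(0)
      while (length(seqs) < k) {
        cand <- paste(sample(digits, len, replace = TRUE), collapse = "-")
        if (!cand %in% seqs) seqs <- c(seqs, cand)
      }
      data.frame(condition = paste0("len", len), payload = seqs,
                 duration_ms = len * 1000 + 2000, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$onset_ms <- cumsum(c(0, df$duration_ms[-nrow(df)])) + 1000
    df$duration_ms <- NULL
    new_trial_schedule(df, "digit_span")
  })
}

#' Task-switching trial schedule
#'
#' Each trial shows a letter-number pair in the top or bottom screen section;
#' the subject responds to a vowel in the top section or an even number in
#' the bottom one. Defaults present 75 letter-target and 75 number-target
#' trials (150 total) in randomized order.
#'
#' @param n_letter,n_number target counts per category.
#' @param seed integer seed for trial order and stimulus sampling.
#' @param iti_ms inter-trial onset spacing in ms.
#' @return a `trial_schedule` with `condition` in `{"letter","number"}`,
#'   columns `position` (`top`/`bottom`) and `go` (correct-response flag).
#' @export
make_task_switching_schedule <- function(n_letter = 75, n_number = 75, seed = NULL,
                                         iti_ms = 2000) {
  if (n_letter < 0 || n_number < 0 || n_letter + n_number < 1)
    stop("at least one target category must have a positive count", call. = FALSE)
  vowels <- c("A", "E", "I", "O", "U")
  consonants <- setdiff(LETTERS, c(vowels, "Y"))
  with_seed(seed, {
    cond <- sample(rep(c("letter", "number"), c(n_letter, n_number)))
    n <- length(cond)
    is_vowel <- stats::runif(n) < 0.5
    letter <- ifelse(is_vowel, sample(vowels, n, replace = TRUE),
                     sample(consonants, n, replace = TRUE))
    number <- sample(1:9, n, replace = TRUE)
    position <- ifelse(cond == "letter", "top", "bottom")
    go <- ifelse(cond == "letter", letter %in% vowels, number %% 2 == 0)
    df <- data.frame(condition = cond,
                     payload = paste0(letter, number),
                     position = position, go = go,
                     onset_ms = seq(0, by = iti_ms, length.out = n) + 1000,
                     stringsAsFactors = FALSE)
    new_trial_schedule(df, "task_switching")
  })
}

#' Face-recognition trial schedule
#'
#' A study set of faces is memorised, then repeated blocks of
#' `sequence_length` faces (each block a permutation of the face pool,
#' containing every studied face) are shown up to `n_trials` trials; the
#' final partial block is truncated. Trials are labelled `known`/`unknown`
#' against the study set.
#'
#' @param n_study study-set size (faces to remember).
#' @param sequence_length faces per block (= face pool size).
#' @param n_trials total trial budget.
#' @param seed integer seed for block permutations.
#' @param iti_ms inter-trial onset spacing in ms.
#' @return a `trial_schedule` with `condition` in `{"known","unknown"}` and
#'   `payload` the face identifier.
#' @export
make_face_recognition_schedule <- function(n_study = 3, sequence_length = 12,
                                           n_trials = 270, seed = NULL,
                                           iti_ms = 1500) {
  if (n_study > sequence_length)
    stop("study-set size cannot exceed the sequence length", call. = FALSE)
  if (n_trials < 1) stop("`n_trials` must be positive", call. = FALSE)
  faces <- sprintf("F%02d", seq_len(sequence_length))
  studied <- faces[seq_len(n_study)]
  n_blocks <- ceiling(n_trials / sequence_length)
  with_seed(seed, {
    shown <- unlist(lapply(seq_len(n_blocks), function(b) sample(faces)))
    shown <- shown[seq_len(n_trials)]
    df <- data.frame(condition = ifelse(shown %in% studied, "known", "unknown"),
                     payload = shown,
                     onset_ms = seq(0, by = iti_ms, length.out = n_trials) + 1000,
                     stringsAsFactors = FALSE)
    new_trial_schedule(df, "face_recognition")
  })
}
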