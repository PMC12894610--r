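# Stimulus-level and subject-level table I/O and validation.
#
# A stimulus table has one row per video: its validated category, mean
# valence and arousal on the 1-9 Likert scale (5 = neutral anchor), the
# fraction of participants endorsing each discrete emotion label
# (multi-select, so rows need not sum to 1), and the five-class classifier
# probability vector (rows must sum to 1).

#' Validate a stimulus table
#'
#' Checks the structural invariants every downstream analysis relies on:
#' unique video ids, categories among [emotion_categories()], valence and
#' arousal within `[1, 9]`, endorsement fractions within `[0, 1]`, and
#' classifier probabilities nonnegative and summing to 1 within `tol` per
#' row.
#'
#' @param stimuli A data frame with columns `video_id`, `category`,
#'   `valence`, `arousal`, `endorse_<category>` (optionally
#'   `endorse_none_of_the_above`) and `prob_<category>`.
#' @param tol Per-row tolerance on the probability simplex constraint.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
#' @examples
#' validate_stimulus_table(simulate_stimuli(seed = 1))
validate_stimulus_table <- function(stimuli, tol = 1e-6) {
  stimuli <- as_tibble(stimuli)
  required <- c("video_id", "category", "valence", "arousal",
                endorse_cols(), prob_cols())
  missing <- setdiff(required, names(stimuli))
  if (length(missing) > 0) {
    abort(paste0("stimulus table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "affectdim_schema_error")
  }
  if (anyDuplicated(stimuli$video_id)) {
    dup <- stimuli$video_id[duplicated(stimuli$video_id)]
    abort(paste0("duplicated video_id: ", paste(unique(dup), collapse = ", ")),
          class = "affectdim_validation_error")
  }
  bad_cat <- setdiff(unique(as.character(stimuli$category)), emotion_categories())
  if (length(bad_cat) > 0) {
    abort(paste0("unknown category value(s): ", paste(bad_cat, collapse = ", ")),
          class = "affectdim_validation_error")
  }
  for (col in c("valence", "arousal")) {
    x <- stimuli[[col]]
    bad <- which(!is.finite(x) | x < 1 | x > 9)
    if (length(bad) > 0) {
      abort(paste0(col, " outside [1, 9] for video_id: ",
                   paste(stimuli$video_id[bad], collapse = ", ")),
            class = "affectdim_validation_error")
    }
  }
  ecols <- intersect(c(endorse_cols(TRUE)), names(stimuli))
  for (col in ecols) {
    x <- stimuli[[col]]
    bad <- which(!is.finite(x) | x < 0 | x > 1)
    if (length(bad) > 0) {
      abort(paste0(col, " outside [0, 1] for video_id: ",
                   paste(stimuli$video_id[bad], collapse = ", ")),
            class = "affectdim_validation_error")
    }
  }
  P <- as.matrix(stimuli[prob_cols()])
  if (any(!is.finite(P)) || any(P < -tol)) {
    bad <- which(apply(P, 1, function(r) any(!is.finite(r) | r < -tol)))
    abort(paste0("negative or non-finite classifier probability for video_id: ",
                 paste(stimuli$video_id[bad], collapse = ", ")),
          class = "affectdim_validation_error")
  }
  s <- rowSums(P)
  off <- which(abs(s - 1) > tol)
  if (length(off) > 0) {
    abort(paste0("classifier probabilities do not sum to 1 (tol ", tol,
                 ") for video_id: ",
                 paste(stimuli$video_id[off], collapse = ", ")),
          class = "affectdim_validation_error")
  }
  stimuli
}

#' Read a stimulus table from CSV
#'
#' Reads a comma-separated, UTF-8, `.`-decimal file with a header row and
#' validates it with [validate_stimulus_table()]. Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param tol Simplex tolerance passed to the validator.
#' @return A validated tibble, one row per video.
#' @export
read_stimulus_table <- function(path, tol = 1e-6) {
  stimuli <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_stimulus_table(stimuli, tol = tol)
}

#' Write a stimulus table to CSV
#'
#' Writes with full-precision decimal rendering so that
#' `read_stimulus_table(write_stimulus_table(x, p))` is the identity on
#' valid tables (round trip preserves differences at the 1e-12 scale).
#' Category values are serialized as the five canonical lowercase tokens.
#'
#' @param stimuli A valid stimulus table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_table <- function(stimuli, path) {
  stimuli <- validate_stimulus_table(stimuli)
  stimuli$category <- as.character(stimuli$category)
  readr::write_csv(stimuli, path, progress = FALSE)
  invisible(path)
}

#' Read a long-format subject ratings table
#'
#' Expects columns `subject_id`, `video_id`, `valence`, `arousal`; one row
#' per (subject, video) pair. Missing ratings (`NA`) are permitted and are
#' ignored when aggregating; duplicate pairs and out-of-range ratings are
#' rejected.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_subject_ratings <- function(path) {
  ratings <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_subject_ratings(ratings)
}

#' Validate a subject ratings table
#'
#' @param ratings Long-format data frame with `subject_id`, `video_id`,
#'   `valence`, `arousal`.
#' @return The validated tibble.
#' @export
validate_subject_ratings <- function(ratings) {
  ratings <- as_tibble(ratings)
  required <- c("subject_id", "video_id", "valence", "arousal")
  missing <- setdiff(required, names(ratings))
  if (length(missing) > 0) {
    abort(paste0("subject ratings missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "affectdim_schema_error")
  }
  key <- paste(ratings$subject_id, ratings$video_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- ratings[duplicated(key), c("subject_id", "video_id")]
    abort(paste0("duplicated (subject, video) pair(s): ",
                 paste(paste0("(", d$subject_id, ", ", d$video_id, ")"),
                       collapse = ", ")),
          class = "affectdim_validation_error")
  }
  for (col in c("valence", "arousal")) {
    x <- ratings[[col]]
    bad <- which(!is.na(x) & (x < 1 | x > 9))
    if (length(bad) > 0) {
      abort(paste0(col, " outside [1, 9] for (subject, video): ",
                   paste(paste0("(", ratings$subject_id[bad], ", ",
                                ratings$video_id[bad], ")"), collapse = ", ")),
            class = "affectdim_validation_error")
    }
  }
  ratings
}

#' Aggregate subject ratings to per-stimulus means
#'
#' Computes the arithmetic mean valence and arousal per video over
#' non-missing subject ratings, mirroring the aggregation of a rater panel
#' into stimulus-level affect norms.
#'
#' @param ratings A validated subject ratings tibble (long format).
#' @return Tibble with `video_id`, `valence`, `arousal`, `n_valence`,
#'   `n_arousal` (rater counts entering each mean).
#' @export
aggregate_ratings <- function(ratings) {
  ratings <- validate_subject_ratings(ratings)
  out <- ratings |>
    group_by(.data$video_id) |>
    summarise(
      n_valence = sum(!is.na(.data$valence)),
      n_arousal = sum(!is.na(.data$arousal)),
      valence = mean(.data$valence, na.rm = TRUE),
      arousal = mean(.data$arousal, na.rm = TRUE),
      .groups = "drop"
    ) |>
    select("video_id", "valence", "arousal", "n_valence", "n_arousal")
  empty <- out$video_id[out$n_valence == 0 | out$n_arousal == 0]
  if (length(empty) > 0) {
    abort(paste0("no non-missing ratings for video_id: ",
                 paste(empty, collapse = ", ")),
          class = "affectdim_validation_error")
  }
  out
}
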