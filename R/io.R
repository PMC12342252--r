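# CSV dialects shared by all pipeline stages. Frames are 0-based on disk.

#' Read and write the landmark CSV dialect
#'
#' Columns: `subject_id`, `hand`, `frame` (0-based), `time_s`, `landmark_id`
#' (0-20), `x`, `y`, `z`; header required.
#'
#' @param path File path.
#' @return `read_landmarks()` returns the landmark tibble.
#' @export
read_landmarks <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    hand = readr::col_character(),
    frame = readr::col_integer(),
    time_s = readr::col_double(),
    landmark_id = readr::col_integer(),
    x = readr::col_double(),
    y = readr::col_double(),
    z = readr::col_double()
  ))
}

#' @rdname read_landmarks
#' @param landmarks Landmark tibble (see [render_landmarks()]).
#' @export
write_landmarks <- function(landmarks, path) {
  readr::write_csv(landmarks, path)
  invisible(path)
}

#' Read and write the signals CSV
#'
#' Columns: `subject_id`, `hand`, `frame` (0-based), `time_s`, and
#' `amplitude` (raw) and/or `amplitude_pct`; an optional `label` column is
#' preserved.
#'
#' @param path File path.
#' @return `read_signals()` returns the signals tibble.
#' @export
read_signals <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    hand = readr::col_character(),
    frame = readr::col_integer(),
    .default = readr::col_double()
  ))
}

#' @rdname read_signals
#' @param signals Signals tibble.
#' @export
write_signals <- function(signals, path) {
  readr::write_csv(signals, path)
  invisible(path)
}

#' Read and write the per-subject features CSV
#'
#' Columns: `subject_id`, `label`, then the 13 features in canonical order
#' (see [feature_columns()]).
#'
#' @param path File path.
#' @return `read_features()` returns the feature tibble.
#' @export
read_features <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    label = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' @rdname read_features
#' @param features Feature tibble.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' Read a ratings CSV (`item_id`, `rater_id`, `rating`)
#'
#' @param path File path.
#' @return Ratings tibble.
#' @export
read_ratings <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    item_id = readr::col_character(),
    rater_id = readr::col_character(),
    rating = readr::col_integer()
  ))
}
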