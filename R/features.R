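#' Per-hand finger-tapping features from detected peaks
#'
#' Summarizes one hand's detected tap peaks into the kinematic feature set:
#' \describe{
#'   \item{ts}{tapping score -- number of taps in the window.}
#'   \item{ta}{mean peak amplitude (percent of full stretch).}
#'   \item{tv}{tapping variation -- SD (n-1 denominator) of peak amplitudes.}
#'   \item{ampd5, ampd7, ampd10}{amplitude decrement -- first-peak amplitude
#'     minus the 5th/7th/10th peak amplitude. When fewer than k peaks exist
#'     the last peak is used (saturating index), keeping vectors complete.}
#' }
#' Hands with fewer than 2 peaks get `tv = 0` and zero decrements plus a
#' quality flag; hands with no peaks are returned as all-NA with the flag.
#'
#' @param peaks Output of [detect_peaks()] (only `type == "peak"` rows are
#'   used), for any number of subject-hand groups.
#' @param duration_s Window duration in seconds (default 10); recorded in the
#'   output for provenance.
#' @return Tibble with one row per subject-hand: `subject_id`, `hand`, `ts`,
#'   `ta`, `tv`, `ampd5`, `ampd7`, `ampd10`, `duration_s`, `flagged`.
#' @examples
#' sig <- generate_hand_signal(hand_params(10, 80), seed = 1)
#' extract_hand_features(detect_peaks(sig))
#' @export
extract_hand_features <- function(peaks, duration_s = 10) {
  stopifnot(all(c("subject_id", "hand", "type", "amplitude_pct")
                %in% names(peaks)))
  pk <- dplyr::filter(peaks, .data$type == "peak")
  pk <- dplyr::arrange(pk, .data$subject_id, .data$hand, .data$index)
  one <- function(a) {
    n <- length(a)
    if (n == 0) {
      return(tibble::tibble(ts = NA_integer_, ta = NA_real_, tv = NA_real_,
                            ampd5 = NA_real_, ampd7 = NA_real_,
                            ampd10 = NA_real_, flagged = TRUE))
    }
    ampd <- function(k) if (n < 2) 0 else a[1] - a[min(k, n)]
    tibble::tibble(
      ts = n, ta = mean(a), tv = if (n < 2) 0 else sd(a),
      ampd5 = ampd(5), ampd7 = ampd(7), ampd10 = ampd(10),
      flagged = n < 2
    )
  }
  out <- dplyr::reframe(
    dplyr::group_by(pk, .data$subject_id, .data$hand),
    one(.data$amplitude_pct)
  )
  out$duration_s <- duration_s
  dplyr::relocate(out, "duration_s", .before = "flagged")
}

#' Combine the two hands of each subject into the 13-feature vector
#'
#' Pivots per-hand features to one row per subject in the canonical column
#' order (see [feature_columns()]) and adds the tapping difference
#' `td = |ts_right - ts_left|`, the inter-hand asymmetry marker of
#' Parkinsonian bradykinesia. Subjects with a flagged or missing hand are
#' dropped with a warning (mirroring exclusion of videos in which taps could
#' not be detected).
#'
#' @param hand_features Output of [extract_hand_features()].
#' @param labels Optional tibble `subject_id`, `label` to join.
#' @return Tibble: `subject_id` (+ `label` if given) and the 13 features.
#' @export
combine_hands <- function(hand_features, labels = NULL) {
  hf <- hand_features
  bad <- unique(hf$subject_id[hf$flagged | is.na(hf$ts)])
  complete <- dplyr::count(dplyr::filter(hf, !.data$flagged), .data$subject_id)
  bad <- union(bad, complete$subject_id[complete$n < 2])
  bad <- union(bad, setdiff(hf$subject_id,
                            complete$subject_id[complete$n == 2]))
  if (length(bad)) {
    warning("excluding ", length(bad),
            " subject(s) with a missing or flagged hand: ",
            paste(utils::head(bad, 5), collapse = ", "))
    hf <- dplyr::filter(hf, !.data$subject_id %in% bad)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(hf, "subject_id", "hand", "ts", "ta", "tv",
                  "ampd5", "ampd7", "ampd10"),
    names_from = "hand",
    values_from = c("ts", "ta", "tv", "ampd5", "ampd7", "ampd10")
  )
  wide$td <- abs(wide$ts_right - wide$ts_left)
  wide <- dplyr::select(wide, "subject_id", dplyr::all_of(FEATURE_COLUMNS))
  if (!is.null(labels)) {
    wide <- dplyr::left_join(wide, dplyr::distinct(labels), by = "subject_id")
    wide <- dplyr::relocate(wide, "label", .after = "subject_id")
  }
  dplyr::arrange(wide, .data$subject_id)
}

#' Build the per-subject feature table from cohort signals
#'
#' Runs the full signal pipeline -- max-normalization, prominence peak
#' detection, per-hand feature extraction, per-subject combination -- over a
#' cohort of tapping signals. Deterministic: same inputs give byte-identical
#' tables.
#'
#' @param x A `tapping_cohort` (from [generate_cohort()]) or a signals tibble
#'   with `subject_id`, `label`, `hand`, `frame`, `time_s` and `amplitude`
#'   (raw) or `amplitude_pct`.
#' @param prominence Unit-scale peak prominence threshold (default 0.3).
#' @return Tibble: `subject_id`, `label`, then the 13 features in canonical
#'   order.
#' @examples
#' cohort <- generate_cohort(n_control = 3, n_pd = 3, seed = 1)
#' build_feature_table(cohort)
#' @export
build_feature_table <- function(x, prominence = 0.3) {
  if (inherits(x, "tapping_cohort")) {
    signals <- x$signals
    duration_s <- x$duration_s
  } else {
    signals <- x
    duration_s <- max(signals$time_s) - min(signals$time_s)
  }
  labels <- if ("label" %in% names(signals)) {
    dplyr::distinct(signals, .data$subject_id, .data$label)
  }
  peaks <- detect_peaks(signals, prominence = prominence)
  hf <- extract_hand_features(peaks, duration_s = duration_s)
  # subject-hands present in the signals but without any detected peak
  universe <- dplyr::distinct(signals, .data$subject_id, .data$hand)
  missing <- dplyr::anti_join(universe, hf, by = c("subject_id", "hand"))
  if (nrow(missing)) {
    hf <- dplyr::bind_rows(hf, dplyr::mutate(
      missing, ts = NA_integer_, ta = NA_real_, tv = NA_real_,
      ampd5 = NA_real_, ampd7 = NA_real_, ampd10 = NA_real_,
      duration_s = duration_s, flagged = TRUE
    ))
  }
  combine_hands(hf, labels = labels)
}
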