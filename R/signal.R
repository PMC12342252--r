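#' Thumb-index fingertip distance from a hand-landmark stream
#'
#' Computes, per frame, the 3-D Euclidean distance between the thumb tip
#' (landmark 4) and the index-finger tip (landmark 8) of the 21-point hand
#' model. This distance is the raw finger-tapping amplitude. All three
#' coordinates are used, including the tracker's relative depth z; no
#' aspect-ratio correction is applied.
#'
#' @param landmarks Tibble with columns `subject_id`, `hand`, `frame`,
#'   `time_s`, `landmark_id` (0-20), `x`, `y`, `z`.
#' @param na_policy What to do with frames whose tip coordinates are missing:
#'   `"fail"` (default) stops; `"drop"` removes the frame with a warning.
#' @param use_z Include the depth coordinate in the distance (default TRUE).
#' @return A signals tibble: `subject_id`, `hand`, `frame`, `time_s`,
#'   `amplitude` (raw units).
#' @examples
#' lm <- render_landmarks(generate_hand_signal(hand_params(10, 80), seed = 1))
#' sig <- tip_distance(lm)
#' @export
tip_distance <- function(landmarks, na_policy = c("fail", "drop"),
                         use_z = TRUE) {
  na_policy <- match.arg(na_policy)
  stopifnot(all(c("subject_id", "hand", "frame", "landmark_id", "x", "y", "z")
                %in% names(landmarks)))
  n_pts <- dplyr::count(landmarks, .data$subject_id, .data$hand, .data$frame)
  if (any(n_pts$n != 21)) {
    stop("every frame must contain exactly 21 landmarks")
  }
  tips <- dplyr::filter(landmarks, .data$landmark_id %in% c(4L, 8L))
  wide <- tidyr::pivot_wider(
    tips,
    id_cols = c("subject_id", "hand", "frame", "time_s"),
    names_from = "landmark_id", values_from = c("x", "y", "z")
  )
  bad <- !stats::complete.cases(wide[c("x_4", "y_4", "z_4", "x_8", "y_8", "z_8")])
  if (any(bad)) {
    if (na_policy == "fail") {
      stop(sum(bad), " frame(s) with missing tip coordinates")
    }
    warning("dropping ", sum(bad), " frame(s) with missing tip coordinates")
    wide <- wide[!bad, ]
  }
  zterm <- if (use_z) (wide$z_4 - wide$z_8)^2 else 0
  out <- tibble::tibble(
    subject_id = wide$subject_id,
    hand = wide$hand,
    frame = wide$frame,
    time_s = wide$time_s,
    amplitude = sqrt((wide$x_4 - wide$x_8)^2 + (wide$y_4 - wide$y_8)^2 + zterm)
  )
  dplyr::arrange(out, .data$subject_id, .data$hand, .data$frame)
}

#' Normalize tapping amplitudes to percent of the per-hand maximum
#'
#' Divides each hand's amplitude series by its own maximum and rescales to
#' 0-100, so 100 marks the widest opening (in practice the instructed
#' pre-tap full stretch). Idempotent on already-normalized input; order and
#' amplitude ratios are preserved.
#'
#' @param signals Signals tibble with an `amplitude` column (raw) and/or an
#'   `amplitude_pct` column (percent).
#' @return The input tibble with an `amplitude_pct` column whose per-hand
#'   maximum is exactly 100.
#' @export
normalize_signal <- function(signals) {
  src <- if ("amplitude" %in% names(signals)) "amplitude" else "amplitude_pct"
  stopifnot(src %in% names(signals))
  out <- dplyr::mutate(
    dplyr::group_by(signals, .data$subject_id, .data$hand),
    .max_amp = max(.data[[src]])
  )
  out <- dplyr::ungroup(out)
  if (any(!is.finite(out$.max_amp)) || any(out$.max_amp <= 0)) {
    stop("degenerate signal: non-positive or non-finite maximum (no tapping present)")
  }
  flat <- dplyr::summarise(
    dplyr::group_by(out, .data$subject_id, .data$hand),
    flat = max(.data[[src]]) == min(.data[[src]]), .groups = "drop"
  )
  if (any(flat$flat)) stop("degenerate signal: constant amplitude series")
  out$amplitude_pct <- 100 * out[[src]] / out$.max_amp
  out$.max_amp <- NULL
  out
}

#' Find peaks of a numeric series by topographic prominence
#'
#' Local maxima (leftmost sample of any flat plateau) whose topographic
#' prominence is at least `min_prominence`. The prominence of a peak is its
#' height minus the higher of the two lowest points one must descend to on
#' the way to higher terrain (or to the series edge) on either side --
#' the standard definition used by signal-processing peak finders. Endpoints
#' are never peaks.
#'
#' @param x Numeric vector (length at least 3).
#' @param min_prominence Minimum prominence, on the same scale as `x`.
#' @return Tibble with `index` (1-based), `value`, `prominence`.
#' @examples
#' find_peaks(c(0, 1, 0.2, 0.8, 0, 1, 0), 0.3)
#' @export
find_peaks <- function(x, min_prominence = 0) {
  if (length(x) < 3) stop("signal must have at least 3 samples")
  if (anyNA(x)) stop("signal contains missing values")
  n <- length(x)

  # local maxima, leftmost sample of plateaus
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) idx <- c(idx, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(idx)) {
    return(tibble::tibble(index = integer(0), value = numeric(0),
                          prominence = numeric(0)))
  }

  prom <- vapply(idx, function(p) {
    h <- x[p]
    left <- if (p > 1L) x[seq_len(p - 1L)] else numeric(0)
    higher <- which(left > h)
    lo_l <- min(x[(if (length(higher)) max(higher) + 1L else 1L):(p - 1L)])
    right <- if (p < n) x[(p + 1L):n] else numeric(0)
    higher_r <- which(right > h)
    stop_r <- if (length(higher_r)) p + min(higher_r) - 1L else n
    lo_r <- min(x[(p + 1L):stop_r])
    h - max(lo_l, lo_r)
  }, numeric(1))

  keep <- prom >= min_prominence
  tibble::tibble(index = idx[keep], value = x[idx[keep]],
                 prominence = prom[keep])
}

#' Detect taps (peaks) and valleys in normalized tapping signals
#'
#' Runs prominence-based peak detection per hand on the percent-scale
#' amplitude signal. The `prominence` argument is expressed on the unit
#' (0-1) scale of the max-normalized signal and rescaled internally to the
#' percent scale, so the default 0.3 requires a tap to rise at least 30% of
#' the full stretch above its surrounding saddle. Valleys are the lowest
#' samples between consecutive accepted peaks.
#'
#' @param signals Signals tibble; normalized automatically (via
#'   [normalize_signal()]) if no `amplitude_pct` column is present.
#' @param prominence Minimum topographic prominence on the unit scale
#'   (default 0.3).
#' @return A tibble with one row per detected extremum: `subject_id`, `hand`,
#'   `type` (`"peak"`/`"valley"`), `index` (1-based position in the hand's
#'   series), `frame`, `time_s`, `amplitude_pct`, `prominence` (NA for
#'   valleys).
#' @examples
#' sig <- generate_hand_signal(hand_params(8, 80), seed = 1)
#' peaks <- detect_peaks(sig)
#' sum(peaks$type == "peak")
#' @export
detect_peaks <- function(signals, prominence = 0.3) {
  stopifnot(prominence >= 0, prominence <= 1)
  if (!"amplitude_pct" %in% names(signals)) {
    signals <- normalize_signal(signals)
  }
  signals <- dplyr::arrange(signals, .data$subject_id, .data$hand, .data$frame)
  one_hand <- function(df) {
    x <- df$amplitude_pct
    pk <- find_peaks(x, min_prominence = prominence * 100)
    if (!nrow(pk)) {
      return(tibble::tibble(type = character(0), index = integer(0),
                            frame = integer(0), time_s = numeric(0),
                            amplitude_pct = numeric(0),
                            prominence = numeric(0)))
    }
    peaks <- tibble::tibble(
      type = "peak", index = pk$index, frame = df$frame[pk$index],
      time_s = df$time_s[pk$index], amplitude_pct = pk$value,
      prominence = pk$prominence / 100
    )
    valleys <- NULL
    if (nrow(pk) >= 2) {
      vidx <- vapply(seq_len(nrow(pk) - 1), function(i) {
        span <- (pk$index[i] + 1L):(pk$index[i + 1] - 1L)
        span[which.min(x[span])]
      }, integer(1))
      valleys <- tibble::tibble(
        type = "valley", index = vidx, frame = df$frame[vidx],
        time_s = df$time_s[vidx], amplitude_pct = x[vidx],
        prominence = NA_real_
      )
    }
    dplyr::arrange(dplyr::bind_rows(peaks, valleys), .data$index)
  }
  out <- dplyr::group_modify(
    dplyr::group_by(signals, .data$subject_id, .data$hand),
    ~ one_hand(.x)
  )
  dplyr::ungroup(out)
}
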