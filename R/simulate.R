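VALLEY_PCT <- 2      # resting thumb-index closure, percent of full stretch
STRETCH_RAW <- 0.35  # full-stretch thumb-index distance in tracker units
LEAD_S <- 0.3        # descent from the instructed pre-tap stretch

#' Generate one hand's synthetic tapping signal
#'
#' Produces a raw thumb-index distance series for a 10-second (by default)
#' finger-tapping trial with commanded kinematics. The series opens with a
#' single full-stretch frame at 100% of the stretch distance -- mirroring the
#' instructed maximal pre-tap stretch -- so that downstream max-normalization
#' anchors commanded percentage amplitudes. It then contains exactly
#' `params$tap_count` raised-cosine open-close cycles between a valley near
#' 2% and commanded peaks whose mean is `amp_mean_pct`, whose SD around the
#' linear trend is `amp_sd_pct`, and whose centred linear trend falls by
#' `decrement_per_tap_pct` per tap. Commanded peaks are clipped to
#' [35, 100]% so every commanded tap clears a 0.3 unit-scale prominence gate.
#' The cycle apex frame carries the commanded peak value exactly; additive
#' Gaussian frame noise (`noise_sd_pct`) is applied everywhere except the
#' anchor frame.
#'
#' @param params A [hand_params()] object.
#' @param fps Frames per second (default 30).
#' @param duration_s Trial duration in seconds (default 10).
#' @param seed Optional integer seed for reproducibility.
#' @param subject_id,hand Identifiers carried into the output.
#' @return A tibble with columns `subject_id`, `hand`, `frame` (0-based),
#'   `time_s`, `amplitude` (raw distance units).
#' @export
generate_hand_signal <- function(params, fps = 30, duration_s = 10,
                                 seed = NULL,
                                 subject_id = "s1", hand = "right") {
  stopifnot(inherits(params, "hand_params"), fps > 0, duration_s > 0)
  n <- round(fps * duration_s)
  if (n < 10) stop("fps * duration_s must be at least 10 frames")
  if (!is.null(seed)) set.seed(seed)

  n_lead <- max(3L, round(LEAD_S * fps))
  n_rem <- n - n_lead

  # inserted halts at valley level between cycles
  halt_after <- integer(0)
  halt_len <- integer(0)
  if (params$halt_prob > 0 && params$tap_count > 1) {
    gaps <- which(runif(params$tap_count - 1) < params$halt_prob)
    if (length(gaps)) {
      halt_after <- gaps
      halt_len <- round(runif(length(gaps), 0.3, 1.0) * fps)
    }
  }
  n_cycles_budget <- n_rem - sum(halt_len)
  if (n_cycles_budget < 3L * params$tap_count) {
    stop("infeasible parameters: ", params$tap_count,
         " taps cannot be represented with >= 3 frames per cycle at ",
         fps, " fps over ", duration_s, " s")
  }

  # jittered cycle lengths (frames), minimum 3, exact total
  w <- rep(1, params$tap_count)
  if (params$timing_jitter_cv > 0) {
    w <- exp(rnorm(params$tap_count, 0, params$timing_jitter_cv))
  }
  lens <- diff(c(0L, round(cumsum(w) / sum(w) * n_cycles_budget)))
  blend <- 0
  while (any(lens < 3L) && blend < 1) {
    blend <- min(1, blend + 0.25)
    wb <- (1 - blend) * w / sum(w) + blend / length(w)
    lens <- diff(c(0L, round(cumsum(wb) * n_cycles_budget)))
  }
  if (any(lens < 3L)) stop("infeasible parameters: cycle shorter than 3 frames")

  # commanded peak amplitudes: centred linear trend + Gaussian spread
  k <- params$tap_count
  trend <- -params$decrement_per_tap_pct * (seq_len(k) - (k + 1) / 2)
  peaks_pct <- params$amp_mean_pct + trend +
    (if (params$amp_sd_pct > 0) rnorm(k, 0, params$amp_sd_pct) else 0)
  peaks_pct <- pmin(100, pmax(35, peaks_pct))

  # assemble: full-stretch anchor, half-cosine descent, then tap cycles
  lead <- 100 - (100 - VALLEY_PCT) * (1 - cos(pi * (0:(n_lead - 1)) / (n_lead - 1))) / 2
  cycles <- vector("list", k)
  for (i in seq_len(k)) {
    L <- lens[i]
    phase <- (0:(L - 1)) / (L - 1)
    cyc <- VALLEY_PCT + (peaks_pct[i] - VALLEY_PCT) * (1 - cos(2 * pi * phase)) / 2
    cyc[which.max(cyc)] <- peaks_pct[i]  # apex carries the commanded peak exactly
    cycles[[i]] <- cyc
    if (length(halt_after) && i %in% halt_after) {
      cycles[[i]] <- c(cyc, rep(VALLEY_PCT, halt_len[match(i, halt_after)]))
    }
  }
  pct <- c(lead, unlist(cycles))
  pct <- c(pct, rep(VALLEY_PCT, n - length(pct)))[seq_len(n)]

  if (params$noise_sd_pct > 0) {
    noise <- rnorm(n, 0, params$noise_sd_pct)
    noise[1] <- 0  # keep the normalization anchor clean
    pct <- pmax(0, pct + noise)
  }

  tibble::tibble(
    subject_id = subject_id,
    hand = hand,
    frame = 0:(n - 1),
    time_s = (0:(n - 1)) / fps,
    amplitude = pct / 100 * STRETCH_RAW
  )
}

#' Generate both hands of one subject
#'
#' @param params A [subject_params()] object.
#' @inheritParams generate_hand_signal
#' @return A list with `signals` (row-bound tibble for both hands, with a
#'   `label` column) and `params`.
#' @export
generate_subject <- function(params, fps = 30, duration_s = 10, seed = NULL,
                             subject_id = "s1") {
  stopifnot(inherits(params, "subject_params"))
  if (!is.null(seed)) set.seed(seed)
  sig <- dplyr::bind_rows(
    generate_hand_signal(params$right, fps, duration_s,
                         subject_id = subject_id, hand = "right"),
    generate_hand_signal(params$left, fps, duration_s,
                         subject_id = subject_id, hand = "left")
  )
  sig$label <- params$label
  list(signals = sig, params = params)
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-subject commanded kinematics from the group presets and renders
#' each hand's tapping signal. One master seed fans out to a per-subject seed
#' sequence, so cohorts are reproducible and subjects are independent.
#'
#' @param n_control,n_pd Number of control and bradykinesia subjects (both
#'   must be at least 1).
#' @param presets A pair of group presets as from [tapping_presets()].
#' @param seed Master integer seed.
#' @param fps,duration_s Recording geometry (default 30 fps, 10 s).
#' @return An object of class `tapping_cohort`: a list with
#'   \describe{
#'     \item{signals}{long tibble: `subject_id`, `label`, `hand`, `frame`,
#'       `time_s`, `amplitude` (raw).}
#'     \item{manifest}{one row per subject-hand with the commanded parameters
#'       (for parameter-recovery checks).}
#'     \item{fps, duration_s, seed}{run geometry.}
#'   }
#' @examples
#' cohort <- generate_cohort(n_control = 3, n_pd = 3, seed = 1)
#' dplyr::count(cohort$manifest, label)
#' @export
generate_cohort <- function(n_control, n_pd,
                            presets = tapping_presets(),
                            seed = 1, fps = 30, duration_s = 10) {
  stopifnot(n_control >= 1, n_pd >= 1)
  set.seed(seed)
  n <- n_control + n_pd
  subject_seeds <- sample.int(.Machine$integer.max, n)
  labels <- c(rep("control", n_control), rep("bradykinesia", n_pd))
  ids <- sprintf("s%03d", seq_len(n))

  out <- vector("list", n)
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    preset <- if (labels[i] == "control") presets$control else presets$pd
    sp <- sample_subject_params(preset, label = labels[i])
    sub <- generate_subject(sp, fps, duration_s, subject_id = ids[i])
    out[[i]] <- sub$signals
    manifest[[i]] <- tibble::tibble(
      subject_id = ids[i],
      label = labels[i],
      hand = c("right", "left"),
      tap_count = c(sp$right$tap_count, sp$left$tap_count),
      amp_mean_pct = c(sp$right$amp_mean_pct, sp$left$amp_mean_pct),
      amp_sd_pct = c(sp$right$amp_sd_pct, sp$left$amp_sd_pct),
      decrement_per_tap_pct = c(sp$right$decrement_per_tap_pct,
                                sp$left$decrement_per_tap_pct),
      halt_prob = c(sp$right$halt_prob, sp$left$halt_prob),
      timing_jitter_cv = c(sp$right$timing_jitter_cv,
                           sp$left$timing_jitter_cv),
      noise_sd_pct = c(sp$right$noise_sd_pct, sp$left$noise_sd_pct),
      tap_count_asymmetry = sp$tap_count_asymmetry
    )
  }
  structure(
    list(
      signals = dplyr::bind_rows(out),
      manifest = dplyr::bind_rows(manifest),
      fps = fps, duration_s = duration_s, seed = seed
    ),
    class = "tapping_cohort"
  )
}

#' Render a tapping signal as a hand-landmark stream
#'
#' Embeds each distance sample as a thumb-tip / index-tip landmark pair (ids
#' 4 and 8) moving vertically, with the remaining 19 landmarks static, so the
#' landmark-to-distance stage of the pipeline can be exercised end to end.
#' Coordinates stay inside the tracker's normalized [0, 1] frame.
#'
#' @param signals Signals tibble with `subject_id`, `hand`, `frame`, `time_s`,
#'   `amplitude` (raw distance units, at most 0.5).
#' @return A landmark tibble: `subject_id`, `hand`, `frame`, `time_s`,
#'   `landmark_id` (0-20), `x`, `y`, `z`.
#' @export
render_landmarks <- function(signals) {
  stopifnot(all(c("subject_id", "hand", "frame", "time_s", "amplitude")
                %in% names(signals)))
  if (any(signals$amplitude > 0.5)) {
    stop("amplitudes above 0.5 cannot be embedded in the unit frame")
  }
  static_ids <- setdiff(0:20, c(4L, 8L))
  static <- tidyr::crossing(
    dplyr::distinct(signals, .data$subject_id, .data$hand, .data$frame,
                    .data$time_s),
    tibble::tibble(
      landmark_id = static_ids,
      x = 0.30 + 0.01 * static_ids,
      y = 0.80,
      z = 0
    )
  )
  tips <- dplyr::bind_rows(
    dplyr::mutate(signals, landmark_id = 4L, x = 0.5, y = 0.55, z = 0),
    dplyr::mutate(signals, landmark_id = 8L, x = 0.5,
                  y = 0.55 - .data$amplitude, z = 0)
  )
  tips <- dplyr::select(tips, "subject_id", "hand", "frame", "time_s",
                        "landmark_id", "x", "y", "z")
  dplyr::arrange(
    dplyr::bind_rows(tips, static),
    .data$subject_id, .data$hand, .data$frame, .data$landmark_id
  )
}
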