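#' Per-hand kinematic parameters for the tapping simulator
#'
#' Bundles the commanded kinematics of one hand performing the 10-second
#' finger-tapping test: how many taps, how wide they open (as a percentage of
#' the initial full thumb-index stretch), how variable the opening is, how
#' fast the amplitude declines across successive taps (the sequence effect),
#' and nuisance terms (halts, timing jitter, frame-level noise).
#'
#' @param tap_count Integer number of open-close tap cycles in the window.
#' @param amp_mean_pct Mean commanded peak amplitude, percent of full stretch.
#' @param amp_sd_pct SD of commanded peak amplitudes around the linear trend,
#'   in percent.
#' @param decrement_per_tap_pct Mean linear decline in commanded peak
#'   amplitude per successive tap, in percent. The trend is centred so the
#'   mean commanded amplitude stays at `amp_mean_pct` while the expected
#'   first-minus-tenth peak difference is `9 * decrement_per_tap_pct`.
#'   May be negative (amplitude growth).
#' @param halt_prob Probability, per inter-tap interval, of an inserted
#'   0.3-1.0 s pause at valley level (hesitations/halts).
#' @param timing_jitter_cv Coefficient of variation of inter-tap intervals.
#' @param noise_sd_pct SD of additive frame-level Gaussian noise, percent.
#'
#' @return A list of class `hand_params`.
#' @examples
#' p <- hand_params(tap_count = 18, amp_mean_pct = 70)
#' sig <- generate_hand_signal(p, seed = 1)
#' @export
hand_params <- function(tap_count,
                        amp_mean_pct,
                        amp_sd_pct = 0,
                        decrement_per_tap_pct = 0,
                        halt_prob = 0,
                        timing_jitter_cv = 0.1,
                        noise_sd_pct = 0) {
  tap_count <- as.integer(round(tap_count))
  stopifnot(
    tap_count >= 1L,
    amp_mean_pct > 0, amp_mean_pct <= 100,
    amp_sd_pct >= 0,
    halt_prob >= 0, halt_prob < 1,
    timing_jitter_cv >= 0,
    noise_sd_pct >= 0
  )
  structure(
    list(
      tap_count = tap_count,
      amp_mean_pct = amp_mean_pct,
      amp_sd_pct = amp_sd_pct,
      decrement_per_tap_pct = decrement_per_tap_pct,
      halt_prob = halt_prob,
      timing_jitter_cv = timing_jitter_cv,
      noise_sd_pct = noise_sd_pct
    ),
    class = "hand_params"
  )
}

#' Group presets for the control and Parkinsonian tapping phenotypes
#'
#' Distributions over per-hand kinematic parameters for two groups: healthy
#' controls and patients with Parkinsonian bradykinesia. Each preset gives,
#' per hand, the between-subject mean and SD of the tap count, the mean peak
#' amplitude, the peak-amplitude SD (tapping variation), and the 1-to-10-tap
#' amplitude decrement, together with the inter-hand tap-count asymmetry mean.
#' Defaults encode group-level summary statistics typical of clinical
#' finger-tapping cohorts: controls tap about 24-25 times per 10 s with wide
#' (about 85%) and stable openings and near-zero asymmetry; the bradykinesia
#' group taps about 18 times with narrower (71-75%), more variable openings,
#' a pronounced amplitude decrement, and larger left-right asymmetry.
#'
#' The asymmetry is modelled as a rounded half-normal; its scale is calibrated
#' numerically so the mean of the rounded draw equals `asymmetry_mean`.
#' Tapping-variation values are commanded after removing the variance the
#' linear decrement itself contributes to the extracted peak-amplitude SD.
#'
#' @param noise_sd_pct Frame-level noise SD (percent) applied to every
#'   generated hand; kept small so landmark jitter does not create spurious
#'   taps.
#' @param timing_jitter_cv Inter-tap-interval coefficient of variation.
#' @param halt_prob Per-interval halt probability (default 0: halts are a
#'   free parameter not constrained by group summary statistics).
#'
#' @return A named list with elements `control` and `pd`, each of class
#'   `group_preset`.
#' @examples
#' presets <- tapping_presets()
#' presets$pd$right$tap_count_mean
#' @export
tapping_presets <- function(noise_sd_pct = 1,
                            timing_jitter_cv = 0.1,
                            halt_prob = 0) {
  hand_row <- function(ts_mean, ts_sd, ta_mean, ta_sd, tv_mean, tv_sd,
                       ampd10_mean, ampd10_sd) {
    list(
      tap_count_mean = ts_mean, tap_count_sd = ts_sd,
      amp_mean = ta_mean, amp_mean_sd = ta_sd,
      tv_mean = tv_mean, tv_sd = tv_sd,
      ampd10_mean = ampd10_mean, ampd10_sd = ampd10_sd
    )
  }
  preset <- function(name, right, left, asymmetry_mean) {
    structure(
      list(
        name = name,
        right = right,
        left = left,
        asymmetry_mean = asymmetry_mean,
        noise_sd_pct = noise_sd_pct,
        timing_jitter_cv = timing_jitter_cv,
        halt_prob = halt_prob
      ),
      class = "group_preset"
    )
  }
  list(
    control = preset(
      "control",
      right = hand_row(24.6, 7.3, 85.4, 6.9, 7.9, 3.9, 2.6, 15.6),
      left  = hand_row(24.6, 7.2, 83.2, 8.0, 8.0, 4.0, 0.4, 11.3),
      asymmetry_mean = 0.4
    ),
    pd = preset(
      "pd",
      right = hand_row(17.9, 7.8, 71.4, 16.0, 14.4, 10.0, 20.5, 28.5),
      left  = hand_row(17.9, 5.6, 75.3, 10.7, 13.1, 8.2, 17.6, 24.6),
      asymmetry_mean = 2.8
    )
  )
}

# scale of a half-normal whose rounded-to-integer mean equals `target`
half_normal_scale_for_rounded_mean <- function(target) {
  if (target <= 0) return(0)
  rounded_mean <- function(sigma) {
    k <- 1:ceiling(8 * sigma + 8)
    # P(round(|Z|sigma) = k) = Phi((k+.5)/sigma) - Phi((k-.5)/sigma), doubled
    sum(k * 2 * (pnorm((k + 0.5) / sigma) - pnorm((k - 0.5) / sigma)))
  }
  uniroot(function(s) rounded_mean(s) - target,
          lower = 1e-6, upper = 10 * target + 10, tol = 1e-10)$root
}

# draw one hand's commanded parameters from a group preset row
sample_hand_params <- function(row, preset, tap_count = NULL) {
  if (is.null(tap_count)) {
    tap_count <- max(5L, as.integer(round(rnorm(1, row$tap_count_mean,
                                                row$tap_count_sd))))
  }
  amp_mean <- min(100, max(35, rnorm(1, row$amp_mean, row$amp_mean_sd)))
  ampd10 <- rnorm(1, row$ampd10_mean, row$ampd10_sd)
  dec <- ampd10 / 9
  tv_target <- max(0, rnorm(1, row$tv_mean, row$tv_sd))
  # the linear trend itself inflates the extracted peak-amplitude SD;
  # command the residual spread so the total matches the drawn target
  trend_var <- dec^2 * (tap_count^2 - 1) / 12
  amp_sd <- sqrt(max(tv_target^2 - trend_var, 0.25))
  hand_params(
    tap_count = tap_count,
    amp_mean_pct = amp_mean,
    amp_sd_pct = amp_sd,
    decrement_per_tap_pct = dec,
    halt_prob = preset$halt_prob,
    timing_jitter_cv = preset$timing_jitter_cv,
    noise_sd_pct = preset$noise_sd_pct
  )
}

#' Draw a subject's commanded parameters from a group preset
#'
#' Samples right-hand kinematics from the preset's right-hand distribution,
#' draws a non-negative integer inter-hand tap-count asymmetry (rounded
#' half-normal calibrated to the preset asymmetry mean), and derives the
#' left-hand tap count as the right count plus or minus that asymmetry.
#' Remaining left-hand kinematics are drawn from the left-hand distribution.
#'
#' @param preset A `group_preset` from [tapping_presets()].
#' @param label Subject label; defaults to `"control"` for the control preset
#'   and `"bradykinesia"` otherwise.
#' @return A list of class `subject_params` with elements `right`, `left`,
#'   `label` and `tap_count_asymmetry`.
#' @export
sample_subject_params <- function(preset, label = NULL) {
  stopifnot(inherits(preset, "group_preset"))
  if (is.null(label)) {
    label <- if (identical(preset$name, "control")) "control" else "bradykinesia"
  }
  sigma <- half_normal_scale_for_rounded_mean(preset$asymmetry_mean)
  asym <- if (sigma > 0) as.integer(round(abs(rnorm(1, 0, sigma)))) else 0L
  right <- sample_hand_params(preset$right, preset)
  left_count <- right$tap_count + sample(c(-1L, 1L), 1) * asym
  if (left_count < 5L) left_count <- right$tap_count + asym
  left <- sample_hand_params(preset$left, preset, tap_count = left_count)
  subject_params(right = right, left = left, label = label)
}

#' Bundle commanded parameters for the two hands of one subject
#'
#' @param right,left `hand_params` objects for each hand.
#' @param label `"control"` or `"bradykinesia"`.
#' @return A list of class `subject_params`; `tap_count_asymmetry` is the
#'   absolute difference of the commanded tap counts.
#' @export
subject_params <- function(right, left, label = c("control", "bradykinesia")) {
  label <- match.arg(label)
  stopifnot(inherits(right, "hand_params"), inherits(left, "hand_params"))
  structure(
    list(
      right = right, left = left, label = label,
      tap_count_asymmetry = abs(right$tap_count - left$tap_count)
    ),
    class = "subject_params"
  )
}
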