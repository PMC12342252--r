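test_that("tip_distance computes 3-D Euclidean distance and basic identities", {
  frame <- function(sid, fr, x4, y4, z4, x8, y8, z8) {
    tibble::tibble(
      subject_id = sid, hand = "right", frame = fr, time_s = fr / 30,
      landmark_id = 0:20,
      x = c(rep(0.2, 4), x4, rep(0.2, 3), x8, rep(0.2, 12)),
      y = c(rep(0.2, 4), y4, rep(0.2, 3), y8, rep(0.2, 12)),
      z = c(rep(0, 4), z4, rep(0, 3), z8, rep(0, 12))
    )
  }
  lm <- dplyr::bind_rows(
    frame("a", 0, 0.3, 0.3, 0, 0.3, 0.3, 0),      # coincident tips
    frame("a", 1, 0, 0, 0, 1, 0, 0),              # unit displacement
    frame("a", 2, 0.1, 0.2, 0, 0.4, 0.6, 0)       # 3-4-5 triangle
  )
  d <- tip_distance(lm)
  expect_equal(d$amplitude, c(0, 1, 0.5))

  # symmetric in the two tips and invariant to rigid translation
  lm_swap <- lm
  lm_swap$landmark_id[lm_swap$landmark_id == 4L] <- 99L
  lm_swap$landmark_id[lm_swap$landmark_id == 8L] <- 4L
  lm_swap$landmark_id[lm_swap$landmark_id == 99L] <- 8L
  expect_equal(tip_distance(lm_swap)$amplitude, d$amplitude)
  lm_shift <- dplyr::mutate(lm, x = x + 0.05, y = y - 0.05, z = z + 0.1)
  expect_equal(tip_distance(lm_shift)$amplitude, d$amplitude)

  # missing tip coordinates: fail by default, droppable by policy
  lm_na <- lm
  lm_na$x[lm_na$frame == 1 & lm_na$landmark_id == 8] <- NA
  expect_error(tip_distance(lm_na), "missing tip")
  expect_warning(d2 <- tip_distance(lm_na, na_policy = "drop"), "dropping")
  expect_equal(nrow(d2), 2)

  lm_short <- dplyr::filter(lm, landmark_id < 20)
  expect_error(tip_distance(lm_short), "21 landmarks")
})

test_that("normalize_signal rescales to max 100, preserves ratios, is idempotent", {
  sig <- tibble::tibble(
    subject_id = "a", hand = "right", frame = 0:2, time_s = 0:2 / 30,
    amplitude = c(1, 2, 4)
  )
  out <- normalize_signal(sig)
  expect_equal(out$amplitude_pct, c(25, 50, 100))

  set.seed(1)
  sig2 <- tibble::tibble(
    subject_id = "a", hand = "left", frame = 0:49, time_s = 0:49 / 30,
    amplitude = runif(50, 0.01, 0.4)
  )
  n1 <- normalize_signal(sig2)
  expect_equal(max(n1$amplitude_pct), 100)
  expect_equal(order(n1$amplitude_pct), order(sig2$amplitude))
  # idempotent on percent-scale input
  n2 <- normalize_signal(dplyr::select(n1, -amplitude))
  expect_equal(n2$amplitude_pct, n1$amplitude_pct)

  flat <- dplyr::mutate(sig, amplitude = 1)
  expect_error(normalize_signal(flat), "degenerate")
  zero <- dplyr::mutate(sig, amplitude = 0)
  expect_error(normalize_signal(zero), "degenerate")
})

test_that("find_peaks handles canonical small cases", {
  # single triangle: one peak with prominence equal to its height
  p <- find_peaks(c(0, 1, 0))
  expect_equal(p$index, 2L)
  expect_equal(p$prominence, 1)

  # strictly monotone signals have no peaks
  expect_equal(nrow(find_peaks(1:10 / 10)), 0)
  expect_equal(nrow(find_peaks(10:1 / 10)), 0)

  # two tall taps around a smaller one; all clear prominence 0.3
  p <- find_peaks(c(0, 1, 0.2, 0.8, 0, 1, 0), 0.3)
  expect_equal(p$index, c(2L, 4L, 6L))
  expect_equal(p$prominence, c(1, 0.6, 1))
  # the middle peak's prominence is measured to its higher saddle
  expect_equal(find_peaks(c(0, 1, 0.2, 0.8, 0, 1, 0))$prominence[2], 0.6)

  # plateau: leftmost sample reported
  p <- find_peaks(c(0, 1, 1, 1, 0))
  expect_equal(p$index, 2L)

  expect_error(find_peaks(c(1, 2)), "at least 3")
})

test_that("find_peaks matches the brute-force prominence oracle on random signals", {
  set.seed(42)
  for (i in 1:200) {
    x <- random_signal(sample(10:200, 1))
    thr <- sample(c(0, 0.2, 0.5, 1), 1)
    got <- find_peaks(x, thr)
    want <- brute_force_peaks(x, thr)
    expect_identical(got$index, want$index)
    expect_equal(got$prominence, want$prominence)
    expect_equal(got$value, x[want$index])
  }
})

test_that("raising the prominence threshold never increases the peak count", {
  set.seed(7)
  for (i in 1:30) {
    x <- random_signal(120)
    counts <- vapply(c(0, 0.1, 0.3, 0.6, 1, 2),
                     function(t) nrow(find_peaks(x, t)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detect_peaks applies the unit-scale threshold on percent signals and interleaves valleys", {
  sig <- generate_hand_signal(hand_params(6, 80, noise_sd_pct = 0), seed = 3)
  ext <- detect_peaks(sig, prominence = 0.3)
  peaks <- dplyr::filter(ext, type == "peak")
  valleys <- dplyr::filter(ext, type == "valley")
  expect_equal(nrow(peaks), 6)
  expect_equal(nrow(valleys), 5)
  # strict interleaving: sorted extrema alternate peak/valley
  expect_true(all(ext$type[order(ext$index)] ==
                    rep(c("peak", "valley"), length.out = nrow(ext))))
  expect_true(all(peaks$prominence >= 0.3))
  expect_true(all(valleys$amplitude_pct < min(peaks$amplitude_pct)))
  # a threshold above every tap's unit prominence removes all peaks
  expect_equal(nrow(dplyr::filter(detect_peaks(sig, prominence = 0.99),
                                  type == "peak")), 0)
})
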