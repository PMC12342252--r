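test_that("generated signals open at full stretch and honour the commanded tap count", {
  p <- hand_params(18, 70, amp_sd_pct = 0, noise_sd_pct = 0)
  sig <- generate_hand_signal(p, seed = 1)
  expect_equal(nrow(sig), 300)
  expect_equal(sig$amplitude[1], max(sig$amplitude))   # anchor frame is the max
  norm <- normalize_signal(sig)
  expect_equal(norm$amplitude_pct[1], 100)
  peaks <- dplyr::filter(detect_peaks(norm), type == "peak")
  expect_equal(nrow(peaks), 18)
  # commanded amplitudes survive max-normalization exactly (apex frames)
  expect_equal(peaks$amplitude_pct, rep(70, 18), tolerance = 1e-12)
})

test_that("noiseless round trip recovers the tap count over random parameter draws", {
  set.seed(99)
  for (i in 1:40) {
    p <- hand_params(
      tap_count = sample(5:60, 1),
      amp_mean_pct = runif(1, 40, 95),
      amp_sd_pct = runif(1, 0, 8),
      decrement_per_tap_pct = runif(1, -1, 2),
      timing_jitter_cv = runif(1, 0, 0.3),
      noise_sd_pct = 0
    )
    sig <- generate_hand_signal(p, seed = i)
    ts <- sum(detect_peaks(sig)$type == "peak")
    expect_identical(ts, p$tap_count)
  }
})

test_that("zero-variation parameters yield zero variation and decrement features", {
  p <- hand_params(12, 75, amp_sd_pct = 0, decrement_per_tap_pct = 0,
                   noise_sd_pct = 0)
  f <- extract_hand_features(detect_peaks(generate_hand_signal(p, seed = 2)))
  expect_equal(f$tv, 0)
  expect_equal(f$ampd10, 0)
  expect_equal(f$ampd5, 0)
})

test_that("linear decrement produces the closed-form first-minus-tenth difference", {
  for (d in c(0.5, 1, 2)) {
    p <- hand_params(15, 70, amp_sd_pct = 0, decrement_per_tap_pct = d,
                     noise_sd_pct = 0)
    f <- extract_hand_features(detect_peaks(generate_hand_signal(p, seed = 5)))
    expect_equal(f$ampd10, 9 * d, tolerance = 1e-10)
    expect_equal(f$ta, 70, tolerance = 1e-10)  # centred trend keeps the mean
  }
})

test_that("expected amplitude decrement is monotone in the commanded decrement", {
  means <- vapply(c(0, 0.5, 1, 1.5, 2), function(d) {
    vals <- vapply(1:12, function(s) {
      p <- hand_params(15, 70, amp_sd_pct = 1, decrement_per_tap_pct = d,
                       noise_sd_pct = 0.5)
      extract_hand_features(detect_peaks(generate_hand_signal(p, seed = s)))$ampd10
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("infeasible tap counts are rejected", {
  expect_error(generate_hand_signal(hand_params(200, 70), fps = 30,
                                    duration_s = 10),
               "infeasible")
})

test_that("halts insert valley-level pauses without changing the tap count", {
  p <- hand_params(10, 80, halt_prob = 0.9, noise_sd_pct = 0)
  sig <- generate_hand_signal(p, seed = 4)
  expect_equal(sum(detect_peaks(sig)$type == "peak"), 10)
})

test_that("subjects honour commanded asymmetry and symmetric hands give TD 0", {
  ph <- function(n) hand_params(n, 80, noise_sd_pct = 0)
  sym <- generate_subject(subject_params(ph(20), ph(20), "control"), seed = 1)
  f <- build_feature_table(dplyr::mutate(sym$signals, label = "control"))
  expect_equal(f$td, 0)

  asym <- generate_subject(subject_params(ph(20), ph(17), "bradykinesia"),
                           seed = 1)
  f2 <- build_feature_table(asym$signals)
  expect_equal(f2$td, 3)
  expect_equal(f2$ts_right, 20)
  expect_equal(f2$ts_left, 17)
})

test_that("cohorts are reproducible, correctly sized and labelled", {
  c1 <- generate_cohort(4, 5, seed = 123)
  c2 <- generate_cohort(4, 5, seed = 123)
  expect_identical(c1$signals, c2$signals)
  expect_identical(c1$manifest, c2$manifest)
  expect_equal(dplyr::n_distinct(c1$signals$subject_id), 9)
  expect_equal(nrow(c1$manifest), 18)  # two hands per subject
  counts <- dplyr::count(dplyr::distinct(c1$signals, subject_id, label), label)
  expect_equal(counts$n[counts$label == "control"], 4)
  expect_equal(counts$n[counts$label == "bradykinesia"], 5)
  c3 <- generate_cohort(4, 5, seed = 124)
  expect_false(identical(c1$signals$amplitude, c3$signals$amplitude))
})

test_that("rendered landmarks reproduce the generated signal through tip_distance", {
  sig <- generate_hand_signal(hand_params(8, 85, noise_sd_pct = 1), seed = 6,
                              subject_id = "sX", hand = "left")
  lm <- render_landmarks(sig)
  expect_equal(dplyr::count(lm, frame)$n, rep(21, 300))
  back <- tip_distance(lm)
  expect_equal(back$amplitude, sig$amplitude, tolerance = 1e-12)
})

test_that("half-normal asymmetry calibration hits the commanded rounded mean", {
  for (target in c(0.4, 1.5, 2.8)) {
    sigma <- tapkin:::half_normal_scale_for_rounded_mean(target)
    k <- 0:200
    m <- sum(k * 2 * (pnorm((k + 0.5) / sigma) - pnorm(pmax(k - 0.5, 0) / sigma)))
    expect_equal(m, target, tolerance = 1e-6)
  }
})
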