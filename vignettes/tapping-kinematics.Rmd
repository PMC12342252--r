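---
title: "Quantifying bradykinesia from finger-tapping kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bradykinesia from finger-tapping kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapkin)
library(dplyr)
```

## The measurement problem

Bradykinesia — slowness of movement with a progressive loss of amplitude in
repetitive actions — is the obligatory motor feature for a clinical diagnosis
of Parkinson's disease. The standard bedside probe is the finger-tapping
test: the subject stretches the index finger against the thumb as far as
possible, then taps thumb and index fingertip together as quickly and as
widely as they can for a fixed window, and a clinician scores the
performance on the ordinal 0–4 MDS-UPDRS item. The rating is subjective and
insensitive to mild impairment.

Markerless hand tracking turns a short smartphone video (30 frames/s, 10 s)
into a quantitative version of the same test: a tracker emits 21 hand
landmarks per frame with coordinates normalized to the image, the
thumb-tip-to-index-tip Euclidean distance becomes a 1-D tapping amplitude
signal, and kinematic features of that signal feed a classifier that screens
for bradykinesia. `tapkin` implements everything downstream of the tracker:
signal construction, tap detection, feature extraction, nested
cross-validated classification, consensus-label construction from multiple
raters, and a synthetic signal generator that makes the whole pipeline
testable without patient video.

## From landmarks to a tapping signal

`tip_distance()` computes the per-frame 3-D Euclidean distance between
landmarks 4 (thumb tip) and 8 (index tip). All three coordinates are used,
including the tracker's relative depth `z`; no aspect-ratio correction is
applied. Both choices are deliberate defaults rather than laws: `use_z`
is an argument, and frames with missing tip coordinates either fail the run
(default) or are dropped under an explicit policy.

`normalize_signal()` divides each hand's series by its own maximum and
rescales to 0–100, so 100 marks the widest opening observed for that hand.
Because subjects are instructed to stretch maximally *before* tapping, the
maximum is in practice the pre-tap stretch, and percentage amplitudes are
comparable across hands and subjects regardless of camera distance. The
transform is idempotent and preserves amplitude ratios; a constant series is
rejected as degenerate (no tapping present).

## Tap detection by topographic prominence

A tap is a local maximum of the amplitude signal whose **topographic
prominence** — its height above the higher of the two saddles separating it
from larger peaks (or from the series edge) — clears a threshold.
`find_peaks()` implements the standard definition directly (leftmost sample
of a flat plateau, endpoints never peaks) and the test suite holds it equal
to an exhaustive brute-force prominence computation on a thousand random
signals.

The threshold is expressed on the unit scale of the normalized signal and
defaults to 0.3. On a 0–100 signal the same geometry corresponds to a
prominence of 30; a threshold of literally 0.3 on the percent scale would
accept frame-level tracking noise as taps, so `detect_peaks()` rescales the
unit threshold to the signal's scale internally. No smoothing is applied
before detection; an optional policy would be easy to add but every
smoothing kernel trades tap-count fidelity for amplitude fidelity, and the
prominence gate already rejects jitter far larger than typical landmark
noise. Valleys are reported as the lowest samples between consecutive
accepted peaks.

## The feature set

Per hand, from the detected peak amplitudes over the 10-s window
(`extract_hand_features()`):

| feature | definition |
|---|---|
| `ts` | tapping score: number of taps |
| `ta` | mean peak amplitude (% of full stretch) |
| `tv` | tapping variation: SD (n−1) of peak amplitudes |
| `ampd5`, `ampd7`, `ampd10` | amplitude decrement: first-peak minus 5th/7th/10th-peak amplitude |

Per subject (`combine_hands()`), the two hands are joined and the **tapping
difference** `td = |ts_right − ts_left|` is added — Parkinson's disease is
an asymmetric condition, and the inter-hand tap-count gap is its most
discriminative single marker here. The flattened vector has exactly 13
features in a fixed, versioned column order (`feature_columns()`).

Three edge policies matter. When fewer than `k` peaks exist, `ampd-k`
saturates at the last peak, keeping vectors complete for classification.
Hands with fewer than two peaks get `tv = 0` and zero decrements plus a
quality flag; subjects with a flagged or absent hand are excluded with a
warning, mirroring the exclusion of videos in which movement could not be
tracked. The first tap is the earliest detected peak — no warm-up peak is
discarded, since the instructed initial stretch anchors the maximum rather
than producing a detectable tap. The decrements are signed, and `td` is
absolute: group means of the inter-hand difference are small positive
numbers in both populations, which a signed mean near zero could not
reproduce.

## The synthetic generator

`generate_hand_signal()` builds a raw distance series as raised-cosine
open–close cycles between a valley near 2% of stretch and commanded peaks,
preceded by a single full-stretch anchor frame at exactly 100%:

* the anchor frame mirrors the instructed pre-tap stretch and pins the
  normalization maximum, so commanded percentage amplitudes survive the
  signal pipeline exactly (the anchor descends monotonically into the first
  valley and is therefore never itself a detected peak);
* each cycle's apex frame carries the commanded peak amplitude exactly,
  so amplitude recovery is not biased by sampling the cosine off-apex;
* commanded peaks follow a **centred** linear trend: the mean stays at
  `amp_mean_pct` while the expected first-minus-tenth difference equals
  `9 × decrement_per_tap_pct`, letting amplitude-mean and decrement targets
  hold simultaneously;
* commanded peaks are clipped to [35, 100]%, so every commanded tap clears
  the 0.3 prominence gate (a peak at 35% over a 2% valley has unit
  prominence ≈ 0.33) and no peak overtakes the anchor;
* inter-tap intervals carry lognormal jitter (`timing_jitter_cv`, default
  0.1 — a free parameter, since interval variability is not constrained by
  the group statistics the presets encode), optional valley-level halts of
  0.3–1.0 s (`halt_prob`, default 0, likewise free), and additive frame
  noise (`noise_sd_pct`, default 1% in the presets) everywhere except the
  anchor frame;
* parameter sets that cannot fit their taps at three or more frames per
  cycle raise an infeasibility error rather than silently distorting.

`tapping_presets()` encodes two group-level distributions over these
parameters — healthy control and Parkinsonian bradykinesia — anchored to
published clinical summary statistics: controls tap ~24.6 (SD 7.3) times
per 10 s at ~85% amplitude with near-zero asymmetry (mean 0.4), the
bradykinesia group ~17.9 taps at 71–75% amplitude with a ~20% first-to-tenth
decrement and asymmetry mean 2.8. Two calibrations connect commanded to
extracted quantities: the commanded within-hand amplitude SD is reduced by
the variance the linear decrement itself contributes to the extracted
peak-amplitude SD, and the integer inter-hand asymmetry is drawn from a
rounded half-normal whose scale is solved numerically so the *rounded* mean
equals the preset mean. `generate_cohort()` draws per-subject parameters
from the presets (right-hand tap count from its distribution, the left-hand
count derived by the drawn asymmetry with random sign) under one master
seed that fans out to per-subject seeds: cohorts are bit-identical across
reruns and subjects are independent.

What the generator does **not** emulate: tremor-frequency content, tracking
dropouts, occlusion, camera motion, or within-trial speed changes beyond
interval jitter. Passing tests therefore demonstrate that the pipeline
recovers commanded kinematics and separates groups *under the modelled
signal family*, not that the classifier's synthetic performance transfers
to patient video.

```{r generator, fig.width = 6, fig.height = 3}
sig <- generate_hand_signal(
  hand_params(tap_count = 12, amp_mean_pct = 70, amp_sd_pct = 8,
              decrement_per_tap_pct = 2, noise_sd_pct = 1),
  seed = 4
)
plot_signal(sig, peaks = detect_peaks(sig))
```

## Classification under nested cross-validation

Six classifier families are evaluated (`nested_cv()`): regularized logistic
regression, SVM, random forest, decision tree, gradient boosting, and
k-nearest neighbours. The protocol is a 5-fold stratified outer loop for
performance estimation wrapped around a 3-fold stratified inner grid search
that selects, per outer fold, the hyperparameter configuration with the
highest mean inner accuracy; the winner is refit on the full outer training
set and evaluated once on the held-out fold. The inner search never touches
outer-test rows — the returned object carries an audit of every row index
each loop accessed, and the tests assert the disjointness on every run.
Training-set AUC is recorded per fold as an overfitting probe (tree
ensembles typically show train AUC ≈ 1 against lower test AUC).

Hyperparameter grids are small, standard desk-scale grids
(`default_grid()`), declared rather than inferred: e.g. SVM over
kernel {linear, radial} × cost {0.1, 1, 10, 100} × gamma {1/13, 0.01, 0.1}.
Scale-sensitive families (SVM, LR, KNN) standardize features with
training-fold statistics only. Scores for AUC come from each model's native
probability or margin (decision values for the SVM, oriented to the
positive class); AUC itself is the midrank Mann–Whitney statistic, exact
under ties. Per-metric fold values are summarized as mean, SD and a 95%
confidence interval from the t-distribution with folds−1 degrees of
freedom — with five folds, mean 0.84 and SD 0.07 this yields 0.75–0.93.
The reported AUC is the mean across outer folds (matching the mean ± SD
reporting convention), not a pooled-prediction AUC. One master seed fans
out to fold-split, model and attribution seeds, all recorded in the result.

Feature influence (`rank_features()`) uses a Monte-Carlo permutation
approximation of Shapley values: for each explained instance and sampled
feature permutation, features switch one at a time from a background draw to
the instance's values and the score changes accumulate per feature. The
reported importance is the mean absolute attribution across the outer-fold
models. Sampling noise scales as 1/√(permutations); the default 24
permutations ranks a dominant feature stably, while near-ties among weak
features can swap order between seeds.

## Consensus labels and rater agreement

Ground truth for screening is clinical: several raters score each video on
the 0–4 finger-tapping item, the per-video consensus is the modal rating
(ties broken toward the higher severity — a screening-oriented choice that
favours sensitivity), and bradykinesia is consensus ≥ 1
(`consensus_labels()`). Agreement across raters is Krippendorff's alpha
(`krippendorff_alpha()`), computed from the coincidence matrix of pairable
values with either the nominal metric or the ordinal cumulative-margin
metric (the default for graded severities); items with a single rating
contribute nothing, missing entries are allowed. `alpha_bootstrap_ci()`
gives a percentile interval from resampling items with replacement (1000
iterations by default), skipping and counting replicates on which alpha is
undefined.

## Numerical choices and problem sizes

* Peak ties on plateaus: leftmost sample, deterministic.
* Grid-search ties: first row of the grid (rows ordered simplest-first).
* `sd` uses the n−1 denominator throughout.
* Degenerate inner splits are re-seeded once, then fail loudly.
* The test suite runs cohorts of 6–100 subjects, parameter-recovery
  Monte-Carlo at 150–300 hands, and 1000-signal oracle sweeps; these sizes
  give Monte-Carlo standard errors a factor of ~3 below the differences the
  tests assert while keeping the default suite fast on one CPU.

## Worked end-to-end run

```{r pipeline}
cohort <- generate_cohort(n_control = 12, n_pd = 12, seed = 7)
features <- build_feature_table(cohort)
fit <- nested_cv(features, "svm", seed = 7)
tidy(fit)
rank_features(fit, n_perm = 8) |> head(4)
```

`run_pipeline()` wraps the same stages into a single reproducible
invocation that serializes its configuration and writes the cohort
manifest, signals, features, report and figures to a run directory.

## Known limitations

* The prominence threshold's scale (unit vs percent) is a modelling
  decision documented above; applied on the percent scale verbatim it would
  change tap counts drastically.
* Group presets encode marginal means and SDs only; the true joint
  distribution of tap count, amplitude, decrement and asymmetry in patients
  is unknown to the simulator, so synthetic class separation may be easier
  than clinical reality.
* Left-hand tap counts are derived from the right-hand draw and the drawn
  asymmetry, so the left marginal SD is slightly inflated relative to its
  preset row; the alternative (independent hands) would break the
  asymmetry distribution, which carries more signal.
* The landmark adapter is an embedding for testing (two moving tips, 19
  static points); it does not model a real tracker's noise structure.
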