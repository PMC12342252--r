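test_that("stratified folds preserve class balance to within one subject", {
  labels <- rep(c("a", "b"), c(50, 50))
  f <- stratified_kfold(labels, 5, seed = 1)
  tab <- table(f, labels)
  expect_true(all(tab == 10))

  labels2 <- rep(c("control", "bradykinesia"), c(47, 53))
  f2 <- stratified_kfold(labels2, 5, seed = 2)
  expect_equal(sort(unique(f2)), 1:5)
  expect_equal(length(f2), 100)           # partition: every subject assigned
  tab2 <- table(f2, labels2)
  expect_true(all(tab2[, "control"] %in% c(9, 10)))
  expect_true(all(tab2[, "bradykinesia"] %in% c(10, 11)))

  expect_error(stratified_kfold(rep(c("a", "b"), c(3, 50)), 5), "at least k")
})

test_that("compute_metrics reproduces a hand-enumerated confusion matrix and rank AUC", {
  m <- compute_metrics(truth = c(1, 1, 0, 0), predicted = c(1, 0, 0, 0),
                       scores = c(0.9, 0.4, 0.6, 0.1), positive = "1")
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$auc, 0.75)

  perfect <- compute_metrics(c("b", "b", "c"), c("b", "b", "c"),
                             c(0.9, 0.8, 0.1), positive = "b")
  expect_true(all(unlist(perfect) == 1))

  # reversing score sign flips the AUC
  set.seed(1)
  truth <- sample(c("control", "bradykinesia"), 40, replace = TRUE)
  sc <- rnorm(40)
  pred <- ifelse(sc > 0, "bradykinesia", "control")
  a1 <- compute_metrics(truth, pred, sc)$auc
  a2 <- compute_metrics(truth, pred, -sc)$auc
  expect_equal(a1 + a2, 1)

  expect_error(compute_metrics(c(1, 1), c(1, 0), c(0.2, 0.3), positive = "1"),
               "single class")
})

test_that("midrank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:10) {
    truth <- sample(c("control", "bradykinesia"), 60, replace = TRUE)
    sc <- round(rnorm(60), 1)  # coarse scores force ties
    if (length(unique(truth)) < 2) next
    got <- compute_metrics(truth, truth, sc)$auc
    want <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = sc, levels = c("control", "bradykinesia"),
      direction = "<", quiet = TRUE
    )))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("summarize_metric matches the closed-form t interval", {
  v <- c(0.8, 0.9, 0.85, 0.8, 0.9)
  s <- summarize_metric(v)
  expect_equal(s$mean, 0.85)
  half <- qt(0.975, 4) * sd(v) / sqrt(5)
  expect_equal(s$ci_low, 0.85 - half)
  expect_equal(s$ci_high, 0.85 + half)

  same <- summarize_metric(rep(0.7, 5))
  expect_equal(same$ci_low, 0.7)
  expect_equal(same$ci_high, 0.7)

  expect_error(summarize_metric(0.5), "at least 2")
})

test_that("nested CV is perfect on separable data for every family", {
  feats <- toy_features(n_per_class = 15, gap = 8, noise = 0.5, seed = 2)
  for (fam in c("lr", "svm", "rf", "dt", "gbm", "knn")) {
    fit <- nested_cv(feats, fam, seed = 3)
    expect_equal(nrow(fit$folds), 5)
    expect_true(all(fit$folds$accuracy == 1), label = fam)
    expect_true(all(fit$folds$auc == 1), label = fam)
  }
})

test_that("nested CV is at chance when labels are independent of features", {
  feats <- toy_features(n_per_class = 30, gap = 0, noise = 1, seed = 4)
  aucs <- vapply(1:3, function(s) {
    glance(nested_cv(feats, "lr", seed = s))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("outer folds partition the cohort and the inner search never sees test rows", {
  feats <- toy_features(n_per_class = 12, gap = 2, seed = 5)
  fit <- nested_cv(feats, "dt", seed = 6)
  test_sets <- lapply(fit$audit, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), seq_len(nrow(feats)))  # disjoint union
  for (a in fit$audit) {
    expect_length(intersect(a$inner_seen, a$test), 0)
    expect_true(all(a$inner_seen %in% a$train))
  }
})

test_that("nested CV is reproducible for a fixed seed and records hyperparameters", {
  feats <- toy_features(n_per_class = 12, gap = 2, seed = 7)
  f1 <- nested_cv(feats, "svm", seed = 11)
  f2 <- nested_cv(feats, "svm", seed = 11)
  expect_equal(f1$folds$auc, f2$folds$auc)
  expect_equal(f1$folds$chosen, f2$folds$chosen)
  expect_equal(nrow(f1$folds$chosen[[1]]), 1)
  expect_true(all(c("kernel", "cost", "gamma") %in%
                    names(f1$folds$chosen[[1]])))
})

test_that("tidy and glance expose fold summaries", {
  feats <- toy_features(n_per_class = 12, gap = 4, seed = 8)
  fit <- nested_cv(feats, "knn", seed = 9)
  td <- tidy(fit)
  expect_true(all(c("metric", "mean", "sd", "ci_low", "ci_high") %in% names(td)))
  expect_true(all(td$ci_low <= td$mean & td$mean <= td$ci_high))
  g <- glance(fit)
  expect_equal(g$family, "knn")
  expect_equal(g$n_folds, 5)
  # overfitting probe: training AUC is reported and bounded sanely
  expect_true(g$train_auc >= g$auc - 2 * sd(fit$folds$auc))
})
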