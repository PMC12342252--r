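#' Stratified k-fold assignment
#'
#' Partitions subjects into k folds preserving the class balance: within each
#' class, shuffled members are dealt round-robin, so per-fold class counts
#' differ from exact proportionality by at most one.
#'
#' @param labels Vector of class labels (two or more classes).
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids (1..k), one per element of `labels`.
#' @examples
#' table(stratified_kfold(rep(c("a", "b"), c(47, 53)), k = 5, seed = 1),
#'       rep(c("a", "b"), c(47, 53)))
#' @export
stratified_kfold <- function(labels, k, seed = 1) {
  stopifnot(k >= 2)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("every class needs at least k = ", k, " members")
  }
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  fold
}

#' Classification metrics for one evaluation fold
#'
#' Accuracy, precision, recall and F1 with bradykinesia (the positive class)
#' as reference, plus the AUC computed as the midrank (Mann-Whitney)
#' statistic of the scores, which handles ties exactly.
#'
#' @param truth Factor or character vector of true labels.
#' @param predicted Predicted labels.
#' @param scores Numeric scores monotone in the positive-class probability.
#' @param positive Positive class (default `"bradykinesia"`).
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`, `auc`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0), c(.9, .4, .6, .1),
#'                 positive = "1")
#' @export
compute_metrics <- function(truth, predicted, scores,
                            positive = "bradykinesia") {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted),
            length(truth) == length(scores))
  if (length(unique(truth)) < 2) {
    stop("AUC undefined: truth contains a single class")
  }
  is_pos <- truth == positive
  tp <- sum(is_pos & predicted == positive)
  fp <- sum(!is_pos & predicted == positive)
  fn <- sum(is_pos & predicted != positive)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  tibble::tibble(
    accuracy = mean(truth == predicted),
    precision = precision, recall = recall, f1 = f1, auc = auc
  )
}

#' Mean, SD and t-based 95% confidence interval of fold metrics
#'
#' The interval is `mean +/- t(0.975, n-1) * sd / sqrt(n)` with `n` the
#' number of folds -- the t-distribution interval with folds-minus-one
#' degrees of freedom.
#'
#' @param values Numeric vector of per-fold metric values (length >= 2).
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `mean`, `sd`, `ci_low`, `ci_high`.
#' @examples
#' summarize_metric(c(0.8, 0.9, 0.85, 0.8, 0.9))
#' @export
summarize_metric <- function(values, conf = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 fold values")
  m <- mean(values)
  s <- sd(values)
  half <- qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  tibble::tibble(mean = m, sd = s, ci_low = m - half, ci_high = m + half)
}

#' Nested cross-validated evaluation of one classifier family
#'
#' Outer stratified k-fold cross-validation estimates generalization
#' performance; within each outer training set an inner stratified k-fold
#' grid search picks the hyperparameter configuration with the highest mean
#' inner accuracy. The winning configuration is refit on the full outer
#' training set and evaluated once on the held-out outer test fold, so the
#' inner search never touches outer-test rows. The training-set AUC is also
#' recorded per fold as an overfitting probe.
#'
#' @param features Feature table from [build_feature_table()]: `subject_id`,
#'   `label`, and the 13 feature columns.
#' @param family Classifier family, see [default_grid()].
#' @param outer_folds,inner_folds Fold counts (defaults 5 and 3).
#' @param grid Hyperparameter grid; defaults to `default_grid(family)`.
#' @param seed Master seed; fans out to fold-split, model and attribution
#'   seeds.
#' @param positive Positive class label.
#' @return An object of class `tapkin_cv` with elements `folds` (per-fold
#'   metrics and chosen hyperparameters), `summary` (per-metric mean/sd/CI),
#'   `roc` (per-fold ROC coordinates), `models`, `audit` (row indices seen by
#'   each loop), and `seeds`. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' cohort <- generate_cohort(12, 12, seed = 1)
#' feats <- build_feature_table(cohort)
#' fit <- nested_cv(feats, "svm", seed = 1)
#' glance(fit)
#' }
#' @export
nested_cv <- function(features, family = MODEL_FAMILIES,
                      outer_folds = 5, inner_folds = 3,
                      grid = NULL, seed = 1,
                      positive = "bradykinesia") {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  stopifnot(nrow(grid) >= 1,
            all(c("subject_id", "label") %in% names(features)),
            all(FEATURE_COLUMNS %in% names(features)))
  if (anyNA(features[FEATURE_COLUMNS])) {
    stop("feature table contains missing values")
  }
  X <- as.matrix(features[FEATURE_COLUMNS])
  rownames(X) <- features$subject_id
  neg <- setdiff(unique(features$label), positive)
  stopifnot(length(neg) == 1)
  y <- factor(features$label, levels = c(neg, positive))

  set.seed(seed)
  seeds <- list(
    outer = sample.int(2^30, 1),
    inner = sample.int(2^30, outer_folds),
    model = sample.int(2^30, outer_folds),
    shap = sample.int(2^30, 1)
  )
  outer <- stratified_kfold(y, outer_folds, seed = seeds$outer)

  folds <- vector("list", outer_folds)
  rocs <- vector("list", outer_folds)
  models <- vector("list", outer_folds)
  audit <- vector("list", outer_folds)
  for (f in seq_len(outer_folds)) {
    test_idx <- which(outer == f)
    train_idx <- which(outer != f)
    ytr <- y[train_idx]

    inner_seen <- integer(0)
    assign_inner <- function(s) stratified_kfold(ytr, inner_folds, seed = s)
    inner <- assign_inner(seeds$inner[f])
    # guard against a degenerate inner split; re-seed once, then fail
    if (any(tapply(ytr, inner, function(v) length(unique(v))) < 2)) {
      inner <- assign_inner(seeds$inner[f] + 1L)
      if (any(tapply(ytr, inner, function(v) length(unique(v))) < 2)) {
        stop("degenerate inner split: single-class inner fold")
      }
    }

    grid_acc <- vapply(seq_len(nrow(grid)), function(g) {
      params <- grid[g, ]
      accs <- vapply(seq_len(inner_folds), function(j) {
        fit_rows <- train_idx[inner != j]
        val_rows <- train_idx[inner == j]
        inner_seen <<- union(inner_seen, c(fit_rows, val_rows))
        m <- fit_model(family, X[fit_rows, , drop = FALSE], y[fit_rows],
                       params, seed = seeds$model[f])
        mean(predict_labels(m, X[val_rows, , drop = FALSE]) == y[val_rows])
      }, numeric(1))
      mean(accs)
    }, numeric(1))
    best <- which.max(grid_acc)  # ties: first (lowest-complexity-first rows)
    chosen <- grid[best, ]

    model <- fit_model(family, X[train_idx, , drop = FALSE], ytr,
                       chosen, seed = seeds$model[f])
    test_scores <- predict_scores(model, X[test_idx, , drop = FALSE])
    test_pred <- predict_labels(model, X[test_idx, , drop = FALSE])
    train_scores <- predict_scores(model, X[train_idx, , drop = FALSE])
    met <- compute_metrics(y[test_idx], test_pred, test_scores,
                           positive = positive)
    train_auc <- compute_metrics(
      ytr, predict_labels(model, X[train_idx, , drop = FALSE]),
      train_scores, positive = positive
    )$auc

    folds[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f), met,
      tibble::tibble(train_auc = train_auc,
                     inner_accuracy = grid_acc[best],
                     chosen = list(chosen))
    )
    rocs[[f]] <- dplyr::mutate(
      roc_points(y[test_idx] == positive, test_scores), fold = f
    )
    models[[f]] <- list(model = model, train_idx = train_idx,
                        test_idx = test_idx)
    audit[[f]] <- list(test = test_idx, train = train_idx,
                       inner_seen = sort(inner_seen))
  }

  fold_tbl <- dplyr::bind_rows(folds)
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc",
                    "train_auc")
  summary <- dplyr::bind_rows(lapply(metric_names, function(mn) {
    dplyr::bind_cols(tibble::tibble(metric = mn),
                     summarize_metric(fold_tbl[[mn]]))
  }))

  structure(
    list(
      family = family, folds = fold_tbl, summary = summary,
      roc = dplyr::bind_rows(rocs), models = models, audit = audit,
      seeds = seeds, positive = positive,
      feature_names = FEATURE_COLUMNS,
      outer_assignment = outer, data = list(X = X, y = y)
    ),
    class = "tapkin_cv"
  )
}

# ROC step coordinates from binary truth and scores (descending threshold)
roc_points <- function(is_pos, scores) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(is_pos[ord])
  fp <- cumsum(!is_pos[ord])
  keep <- !duplicated(scores[ord], fromLast = TRUE)  # one point per threshold
  tibble::tibble(
    fpr = c(0, fp[keep] / sum(!is_pos)),
    tpr = c(0, tp[keep] / sum(is_pos))
  )
}

#' Evaluate several classifier families on one feature table
#'
#' @param features Feature table.
#' @param families Character vector of families (default: all six).
#' @param ... Passed to [nested_cv()].
#' @return Named list of `tapkin_cv` objects.
#' @export
evaluate_families <- function(features, families = MODEL_FAMILIES, ...) {
  res <- lapply(families, function(f) nested_cv(features, f, ...))
  names(res) <- families
  res
}

#' @export
print.tapkin_cv <- function(x, ...) {
  cat("Nested CV (", length(x$audit), " outer folds): family ",
      toupper(x$family), "\n", sep = "")
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' @rdname nested_cv
#' @param x A `tapkin_cv` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tapkin_cv <- function(x, ...) x$summary

#' @rdname nested_cv
#' @exportS3Method generics::glance
glance.tapkin_cv <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    family = x$family,
    n_folds = nrow(x$folds),
    accuracy = s$mean[s$metric == "accuracy"],
    auc = s$mean[s$metric == "auc"],
    train_auc = s$mean[s$metric == "train_auc"]
  )
}
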