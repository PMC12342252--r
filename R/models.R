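# Classifier backends behind a uniform fit/score interface.
#
# Each backend fits on a numeric matrix X and factor y (levels: negative,
# positive) and must return scores monotone in the probability of the
# positive class. Scale-sensitive families (SVM, LR, KNN) standardize using
# training-set statistics only, so resampling never leaks test information.

MODEL_FAMILIES <- c("lr", "svm", "rf", "dt", "gbm", "knn")

#' Default hyperparameter grids per classifier family
#'
#' Small, standard grids searched by the inner loop of [nested_cv()]:
#' regularized logistic regression (`lr`: lambda), support vector machine
#' (`svm`: kernel, cost, gamma), random forest (`rf`: trees, depth), decision
#' tree (`dt`: depth), gradient boosting (`gbm`: learning rate, rounds), and
#' k-nearest neighbours (`knn`: k).
#'
#' @param family One of `"lr"`, `"svm"`, `"rf"`, `"dt"`, `"gbm"`, `"knn"`.
#' @return A tibble, one row per candidate configuration.
#' @export
default_grid <- function(family = MODEL_FAMILIES) {
  family <- match.arg(family)
  switch(family,
    lr = tidyr::crossing(lambda = c(1, 0.1, 0.01, 0.001)),
    svm = dplyr::bind_rows(
      tidyr::crossing(kernel = "linear", cost = c(0.1, 1, 10, 100),
                      gamma = NA_real_),
      tidyr::crossing(kernel = "radial", cost = c(0.1, 1, 10, 100),
                      gamma = c(NA, 0.01, 0.1))  # NA = 1/n_features
    ),
    rf = tidyr::crossing(num_trees = c(100, 300), max_depth = c(0, 3, 5)),
    dt = tidyr::crossing(maxdepth = c(30, 3, 5, 10)),
    gbm = tidyr::crossing(eta = c(0.05, 0.1), nrounds = c(100, 300)),
    knn = tidyr::crossing(k = c(3, 5, 7, 9))
  )
}

fit_model <- function(family, X, y, params, seed = 1) {
  pos <- levels(y)[2]
  set.seed(seed)
  fit <- switch(family,
    lr = {
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = params$lambda)
    },
    svm = {
      gamma <- if (is.na(params$gamma)) 1 / ncol(X) else params$gamma
      e1071::svm(X, y, kernel = params$kernel, cost = params$cost,
                 gamma = gamma, scale = TRUE)
    },
    rf = {
      ranger::ranger(
        x = X, y = y, probability = TRUE,
        num.trees = params$num_trees,
        max.depth = if (params$max_depth == 0) NULL else params$max_depth,
        seed = seed, num.threads = 1
      )
    },
    dt = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = params$maxdepth,
                                                  cp = 0.001, xval = 0))
    },
    gbm = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y == pos))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = params$eta,
                      max_depth = 3, nthread = 1, tree_method = "exact"),
        data = dtrain, nrounds = params$nrounds, verbose = 0
      )
    },
    knn = {
      ctr <- colMeans(X)
      scl <- apply(X, 2, sd)
      scl[scl == 0] <- 1
      list(X = scale(X, ctr, scl), y = y, k = params$k, ctr = ctr, scl = scl)
    },
    stop("unknown family: ", family)
  )
  structure(list(family = family, fit = fit, levels = levels(y)),
            class = "tapkin_model")
}

# score for the positive class (second level of y at fit time)
predict_scores <- function(model, X) {
  pos <- model$levels[2]
  fit <- model$fit
  switch(model$family,
    lr = as.numeric(predict(fit, newx = X, type = "response")),
    svm = {
      pr <- predict(fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # column name "A/B" means positive decision values favour class A
      first <- strsplit(colnames(dv)[1], "/")[[1]][1]
      if (identical(first, pos)) as.numeric(dv) else -as.numeric(dv)
    },
    rf = predict(fit, data = X, num.threads = 1)$predictions[, pos],
    dt = predict(fit, newdata = as.data.frame(X), type = "prob")[, pos],
    gbm = as.numeric(predict(fit, xgboost::xgb.DMatrix(X))),
    knn = {
      Xs <- scale(X, fit$ctr, fit$scl)
      pr <- class::knn(fit$X, Xs, fit$y, k = fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == pos, p, 1 - p)
    }
  )
}

predict_labels <- function(model, X) {
  fit <- model$fit
  switch(model$family,
    lr = factor(ifelse(predict_scores(model, X) > 0.5,
                       model$levels[2], model$levels[1]),
                levels = model$levels),
    svm = factor(predict(fit, X), levels = model$levels),
    rf = {
      pr <- predict(fit, data = X, num.threads = 1)$predictions
      factor(colnames(pr)[max.col(pr, ties.method = "first")],
             levels = model$levels)
    },
    dt = factor(as.character(predict(fit, newdata = as.data.frame(X),
                                     type = "class")),
                levels = model$levels),
    gbm = factor(ifelse(predict_scores(model, X) > 0.5,
                        model$levels[2], model$levels[1]),
                 levels = model$levels),
    knn = {
      Xs <- scale(X, fit$ctr, fit$scl)
      factor(as.character(class::knn(fit$X, Xs, fit$y, k = fit$k)),
             levels = model$levels)
    }
  )
}
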