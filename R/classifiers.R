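# Binary classifier wrappers behind one fit/predict surface.
# X is always a numeric matrix (subjects x selected features), already
# standardized by the caller; y is a logical "positive class" (ADHD) vector.
# Predictions are P(positive).

CLASSIFIER_NAMES <- c("logistic_regression", "svm", "decision_tree",
                      "naive_bayes", "knn", "random_forest")

#' Default hyperparameter grid for a classifier family
#'
#' Small fixed grids, one row per candidate: ridge penalty for logistic
#' regression, kernel x cost for the SVM, tree depth, Laplace smoothing
#' (a single point: Gaussian naive Bayes has no tunable of consequence),
#' neighbour count for KNN, and mtry for the random forest.
#'
#' @param name Classifier family name, one of `logistic_regression`,
#'   `svm`, `decision_tree`, `naive_bayes`, `knn`, `random_forest`.
#' @return A data frame of candidate hyperparameter rows.
#' @export
default_grid <- function(name) {
  switch(name,
    logistic_regression = data.frame(lambda = c(0.001, 0.01, 0.1, 1)),
    svm = expand.grid(kernel = c("linear", "radial"), cost = c(0.1, 1, 10),
                      stringsAsFactors = FALSE),
    decision_tree = data.frame(maxdepth = c(2, 3, 5, 30)),
    naive_bayes = data.frame(laplace = 0),
    knn = data.frame(k = c(3, 5, 7)),
    random_forest = expand.grid(mtry = c(2, 3), ntree = 200),
    stop(sprintf("unknown classifier '%s'", name), call. = FALSE))
}

#' Specify a classifier for nested cross-validation
#'
#' @param name Classifier family, one of `logistic_regression`, `svm`,
#'   `decision_tree`, `naive_bayes`, `knn`, `random_forest`.
#' @param grid Hyperparameter candidates (data frame, one row per
#'   candidate); defaults to [default_grid()].
#' @param inner_folds Inner CV folds for tuning (default 5).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(name, grid = NULL, inner_folds = 5L) {
  name <- match.arg(name, CLASSIFIER_NAMES)
  if (is.null(grid)) grid <- default_grid(name)
  grid <- as.data.frame(grid)
  if (!nrow(grid)) stop("hyperparameter grid must be non-empty", call. = FALSE)
  structure(list(name = name, grid = grid,
                 inner_folds = as.integer(inner_folds)),
            class = "classifier_spec")
}

as_pos_factor <- function(y) factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))

grid_key <- function(params) {
  paste(sprintf("%s=%s", names(params), vapply(params, format, character(1))),
        collapse = ",")
}

fit_classifier <- function(name, X, y, params) {
  yf <- as_pos_factor(y)
  fit <- switch(name,
    logistic_regression = {
      X2 <- if (ncol(X) < 2) cbind(X, .pad = 0) else X
      # short descending path ending at the requested penalty keeps the
      # coordinate-descent solver well behaved for a single lambda
      path <- params$lambda * c(16, 8, 4, 2, 1)
      withCallingHandlers(
        glmnet::glmnet(X2, yf, family = "binomial", alpha = 0, lambda = path),
        warning = function(w) {
          # inherent to folds this small; not actionable per fit
          if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    },
    svm = {
      tryCatch(
        e1071::svm(X, yf, kernel = params$kernel, cost = params$cost,
                   scale = FALSE, probability = TRUE),
        error = function(e)
          e1071::svm(X, yf, kernel = params$kernel, cost = params$cost,
                     scale = FALSE))
    },
    decision_tree = {
      df <- data.frame(.y = yf, X, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = params$maxdepth,
                                                  minsplit = 4, cp = 0,
                                                  xval = 0))
    },
    naive_bayes = e1071::naiveBayes(as.data.frame(X), yf,
                                    laplace = params$laplace),
    knn = list(X = X, y = yf, k = min(params$k, nrow(X))),
    random_forest = randomForest::randomForest(
      X, yf, ntree = params$ntree, mtry = min(params$mtry, ncol(X))),
    stop(sprintf("unknown classifier '%s'", name), call. = FALSE))
  structure(list(name = name, fit = fit, params = params,
                 feature_names = colnames(X)),
            class = "ps_model")
}

predict_classifier <- function(model, Xnew) {
  fit <- model$fit
  switch(model$name,
    logistic_regression = {
      X2 <- if (ncol(Xnew) < 2) cbind(Xnew, .pad = 0) else Xnew
      as.numeric(stats::predict(fit, newx = X2, s = model$params$lambda,
                                type = "response"))
    },
    svm = {
      pr <- stats::predict(fit, Xnew, probability = !is.null(fit$probA))
      probs <- attr(pr, "probabilities")
      if (!is.null(probs) && "pos" %in% colnames(probs)) {
        as.numeric(probs[, "pos"])
      } else {
        # Platt scaling unavailable (degenerate training fold): squash the
        # margin instead. Decision values are signed for the level named
        # first in the "a/b" column label.
        dvm <- attr(stats::predict(fit, Xnew, decision.values = TRUE),
                    "decision.values")
        sgn <- if (startsWith(colnames(dvm)[1], "pos")) 1 else -1
        stats::plogis(sgn * dvm[, 1])
      }
    },
    decision_tree = {
      df <- as.data.frame(Xnew)
      names(df) <- model$feature_names
      stats::predict(fit, newdata = df, type = "prob")[, "pos"]
    },
    naive_bayes = {
      df <- as.data.frame(Xnew)
      names(df) <- model$feature_names
      stats::predict(fit, df, type = "raw")[, "pos"]
    },
    knn = {
      pred <- class::knn(fit$X, Xnew, cl = fit$y, k = fit$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "pos", p, 1 - p)
    },
    random_forest = stats::predict(fit, Xnew, type = "prob")[, "pos"])
}
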