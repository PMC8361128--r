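#' Threshold-based and ranking metrics for a binary diagnostic classifier
#'
#' Sensitivity (true-positive rate), specificity (true-negative rate) and
#' accuracy are computed at a fixed probability threshold; AUROC uses the
#' rank-statistic (Mann-Whitney) formulation with half credit for score
#' ties, so it is threshold-free.
#'
#' @param y_true Logical vector, `TRUE` for the positive (ADHD) class;
#'   both classes must be present.
#' @param y_score Numeric scores / predicted probabilities of the positive
#'   class.
#' @param threshold Decision threshold on the score (default 0.5).
#' @return Named list: `sensitivity`, `specificity`, `accuracy`, `auroc`.
#' @export
binary_metrics <- function(y_true, y_score, threshold = 0.5) {
  y_true <- as.logical(y_true)
  if (!any(y_true) || all(y_true)) {
    stop("both classes must be present in y_true", call. = FALSE)
  }
  pred <- y_score >= threshold
  tp <- sum(pred & y_true); fn <- sum(!pred & y_true)
  tn <- sum(!pred & !y_true); fp <- sum(pred & !y_true)
  r <- rank(y_score)
  n1 <- sum(y_true); n0 <- sum(!y_true)
  auroc <- (sum(r[y_true]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(y_true),
       auroc = auroc)
}

#' Empirical ROC curve from pooled scores
#'
#' Sweeps the decision threshold over the distinct score values (descending)
#' and returns the (FPR, TPR) staircase from (0,0) to (1,1); tied scores
#' move both coordinates together, which makes the trapezoidal area equal
#' to the tie-aware rank AUROC of [binary_metrics()].
#'
#' @inheritParams binary_metrics
#' @return Data frame with columns `fpr`, `tpr`, both monotone
#'   non-decreasing.
#' @export
pooled_roc <- function(y_true, y_score) {
  y_true <- as.logical(y_true)
  o <- order(y_score, decreasing = TRUE)
  ys <- y_score[o]; yt <- y_true[o]
  keep <- !duplicated(ys, fromLast = TRUE)   # last index of each tie block
  tpr <- cumsum(yt)[keep] / sum(yt)
  fpr <- cumsum(!yt)[keep] / sum(!yt)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under an ROC curve
#' @param roc Data frame with `fpr`, `tpr` as from [pooled_roc()].
#' @return The area, a number in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# stratified fold assignment: within each class, shuffle then deal
# round-robin, so fold sizes differ by at most one per class
make_stratified_folds <- function(positive, k) {
  fold <- integer(length(positive))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(positive == cls)
    if (length(idx) < k && cls %in% positive) {
      stop(sprintf("class with %d members cannot fill %d folds",
                   length(idx), k), call. = FALSE)
    }
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# Feature selection, standardization, inner-CV tuning and the final refit,
# all computed from the training rows alone. Held-out data never enters.
train_fold_model <- function(X_train, y_train, spec, k_select) {
  af <- anova_f_columns(X_train, y_train)
  ord <- order(af$p, colnames(X_train))
  features <- colnames(X_train)[ord][seq_len(k_select)]
  Xs <- X_train[, features, drop = FALSE]
  ctr <- colMeans(Xs)
  scl <- apply(Xs, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(Xs, center = ctr, scale = scl)

  grid <- spec$grid
  if (nrow(grid) > 1) {
    inner_fold <- make_stratified_folds(y_train, spec$inner_folds)
    scores <- matrix(NA_real_, nrow(Xs), nrow(grid))
    for (fi in seq_len(spec$inner_folds)) {
      tr <- inner_fold != fi
      if (length(unique(y_train[tr])) < 2 || !any(!tr)) next
      for (gi in seq_len(nrow(grid))) {
        m <- fit_classifier(spec$name, Xs[tr, , drop = FALSE], y_train[tr],
                            as.list(grid[gi, , drop = FALSE]))
        scores[!tr, gi] <- predict_classifier(m, Xs[!tr, , drop = FALSE])
      }
    }
    auc <- apply(scores, 2, function(s) {
      ok <- !is.na(s)
      if (length(unique(y_train[ok])) < 2) return(0.5)
      binary_metrics(y_train[ok], s[ok])$auroc
    })
    best <- which.max(auc)   # first grid row wins ties: deterministic
  } else {
    best <- 1L
  }
  params <- as.list(grid[best, , drop = FALSE])
  model <- fit_classifier(spec$name, Xs, y_train, params)
  list(features = features, center = ctr, scale = scl,
       params = params, model = model)
}

#' Repeated nested stratified cross-validation of a binary classifier
#'
#' For each repetition (freshly shuffled stratified outer folds): per outer
#' fold, the top-`k_select` features are chosen by the one-way ANOVA F
#' filter on the training rows only, standardization is fitted on the
#' training rows only, hyperparameters are tuned by stratified inner CV
#' maximizing AUROC of the pooled inner out-of-fold scores, the winning
#' configuration is refitted on the whole training fold, and the held-out
#' fold is scored. Per-repetition metrics come from the pooled out-of-fold
#' predictions; the aggregate is the mean over repetitions with a
#' half-width (standard error by default, 95% t-interval with
#' `ci = "ci95"`).
#'
#' @param fm A `feature_matrix` with both groups present and at least
#'   `outer_folds` subjects per class.
#' @param spec A [classifier_spec()].
#' @param outer_folds Outer folds (default 10).
#' @param k_select Features selected per outer fold (default 9).
#' @param repetitions Number of repeated CV runs (default 40; the study
#'   protocol calls for 30-50).
#' @param seed Integer seed; repetition `r` uses a seed drawn from a stream
#'   initialized with `seed`, so results are reproducible end to end.
#' @param ci `"se"` (standard error, default) or `"ci95"`.
#' @param perturb_test Optional audit hook: a function applied to the
#'   held-out design matrix AFTER selection, tuning and fitting, just
#'   before prediction. Used by the leakage guard to prove held-out data
#'   never influences training; `NULL` (default) disables it.
#' @return An `evaluation_report`: list with `classifier`,
#'   `per_repetition` (data frame of metrics), `aggregate` (metric, mean,
#'   half_width), `ci_mode`, `roc_points` (pooled per repetition),
#'   `selected_features` (repetition, fold, rank, feature) and
#'   `fold_params` (repetition, fold, params key).
#' @export
nested_cv <- function(fm, spec, outer_folds = 10L, k_select = 9L,
                      repetitions = 40L, seed = 1L, ci = c("se", "ci95"),
                      perturb_test = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "classifier_spec"))
  ci <- match.arg(ci)
  X <- feature_values(fm)
  y <- fm$group == "ADHD"
  if (length(unique(fm$group)) != 2) stop("both groups required", call. = FALSE)
  if (k_select > ncol(X)) {
    stop(sprintf("k_select = %d exceeds the %d available features",
                 k_select, ncol(X)), call. = FALSE)
  }
  if (min(sum(y), sum(!y)) < outer_folds) {
    stop("each class needs at least one subject per outer fold", call. = FALSE)
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  rep_seeds <- sample.int(2^30, repetitions)

  per_rep <- vector("list", repetitions)
  roc_list <- vector("list", repetitions)
  sel_list <- list()
  par_list <- list()
  for (r in seq_len(repetitions)) {
    set.seed(rep_seeds[r])
    fold <- make_stratified_folds(y, outer_folds)
    score <- rep(NA_real_, length(y))
    for (fi in seq_len(outer_folds)) {
      test <- fold == fi
      fit <- train_fold_model(X[!test, , drop = FALSE], y[!test], spec,
                              k_select)
      Xt <- X[test, fit$features, drop = FALSE]
      if (!is.null(perturb_test)) {
        # the audit hook must not disturb the training RNG stream
        rs <- get(".Random.seed", envir = globalenv())
        Xt <- perturb_test(Xt)
        assign(".Random.seed", rs, envir = globalenv())
      }
      Xt <- scale(Xt, center = fit$center, scale = fit$scale)
      score[test] <- predict_classifier(fit$model, Xt)
      sel_list[[length(sel_list) + 1L]] <-
        data.frame(repetition = r, fold = fi,
                   rank = seq_along(fit$features), feature = fit$features)
      par_list[[length(par_list) + 1L]] <-
        data.frame(repetition = r, fold = fi, params = grid_key(fit$params))
    }
    m <- binary_metrics(y, score)
    per_rep[[r]] <- data.frame(repetition = r, seed = rep_seeds[r],
                               sensitivity = m$sensitivity,
                               specificity = m$specificity,
                               auroc = m$auroc, accuracy = m$accuracy)
    roc <- pooled_roc(y, score)
    roc_list[[r]] <- cbind(repetition = r, roc)
  }
  per_rep <- do.call(rbind, per_rep)
  metrics <- c("sensitivity", "specificity", "auroc", "accuracy")
  hw_mult <- if (ci == "se") 1 else
    stats::qt(0.975, df = max(repetitions - 1, 1))
  agg <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(mm) mean(per_rep[[mm]]), numeric(1)),
    half_width = vapply(metrics, function(mm) {
      if (repetitions < 2) return(0)
      hw_mult * stats::sd(per_rep[[mm]]) / sqrt(repetitions)
    }, numeric(1)))
  rownames(agg) <- NULL
  structure(list(classifier = spec$name,
                 per_repetition = per_rep,
                 aggregate = agg,
                 ci_mode = ci,
                 roc_points = do.call(rbind, roc_list),
                 selected_features = do.call(rbind, sel_list),
                 fold_params = do.call(rbind, par_list)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, %d repetitions (half-width: %s)\n",
              x$classifier, nrow(x$per_repetition), x$ci_mode))
  for (i in seq_len(nrow(x$aggregate))) {
    cat(sprintf("  %-11s %.3f (+/- %.3f)\n", x$aggregate$metric[i],
                x$aggregate$mean[i], x$aggregate$half_width[i]))
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  out <- list(classifier = report$classifier,
              ci_mode = report$ci_mode,
              aggregate = report$aggregate,
              per_repetition = report$per_repetition,
              selected_features = report$selected_features,
              fold_params = report$fold_params)
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
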