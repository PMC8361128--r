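test_that("binary metrics handle the tie and perfect-ordering conventions", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  same <- binary_metrics(y, rep(0.5, 4))
  expect_equal(same$auroc, 0.5)

  perfect <- binary_metrics(y, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$auroc, 1.0)
  expect_equal(perfect$sensitivity, 1.0)
  expect_equal(perfect$specificity, 1.0)

  expect_error(binary_metrics(rep(TRUE, 4), runif(4)), "both classes")
})

test_that("rank AUROC equals the trapezoidal area and the U statistic", {
  set.seed(51)
  for (case in 1:8) {
    y <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.45, 0.55))
    if (!any(y) || all(y)) next
    s <- round(runif(40), 2)   # ties on purpose
    m <- binary_metrics(y, s)
    expect_equal(m$auroc, oracle_auroc_trapezoid(y, s), tolerance = 1e-12)
    expect_equal(m$auroc, roc_auc(pooled_roc(y, s)), tolerance = 1e-12)
    u <- mann_whitney_u(s[y], s[!y])$U
    expect_equal(m$auroc, u / (sum(y) * sum(!y)), tolerance = 1e-12)
  }
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  set.seed(52)
  y <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  s <- runif(30)
  m <- binary_metrics(y, s)
  expect_equal(m$accuracy,
               (m$sensitivity * sum(y) + m$specificity * sum(!y)) / 30)
  expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
})

test_that("the pooled ROC staircase is monotone from (0,0) to (1,1)", {
  set.seed(53)
  y <- rep(c(TRUE, FALSE), 15)
  roc <- pooled_roc(y, runif(30))
  expect_equal(roc[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(as.numeric(roc[nrow(roc), ]), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))

  perfect <- pooled_roc(y, as.numeric(y))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))

  flat <- pooled_roc(y, rep(0.3, 30))
  expect_equal(flat, data.frame(fpr = c(0, 1), tpr = c(0, 1)))
})

test_that("a perfectly separating feature yields perfect metrics every repetition", {
  n <- 20
  fm <- feature_matrix(sprintf("s%02d", 1:n),
                       rep(c("ADHD", "CTRL"), each = n / 2),
                       matrix(as.numeric(rep(c(1, 0), each = n / 2)),
                              ncol = 1),
                       "oracle_feature")
  rep <- nested_cv(fm, classifier_spec("decision_tree"), outer_folds = 5,
                   k_select = 1, repetitions = 3, seed = 3)
  expect_true(all(rep$per_repetition$auroc == 1))
  expect_true(all(rep$per_repetition$sensitivity == 1))
  expect_true(all(rep$per_repetition$specificity == 1))
})

test_that("exactly k features are selected in every outer fold", {
  fm <- strong_fm()
  rep <- nested_cv(fm, classifier_spec("logistic_regression",
                                       grid = data.frame(lambda = 0.1)),
                   outer_folds = 10, k_select = 9, repetitions = 2, seed = 4)
  counts <- table(rep$selected_features$repetition,
                  rep$selected_features$fold)
  expect_true(all(counts == 9))
  expect_equal(nrow(unique(rep$selected_features[, c("repetition", "fold")])),
               2 * 10)
})

test_that("held-out data never influences selection, tuning or fitting", {
  fm <- strong_fm()
  base <- nested_cv(fm, classifier_spec("svm"), outer_folds = 5,
                    k_select = 5, repetitions = 2, seed = 11)
  noised <- nested_cv(fm, classifier_spec("svm"), outer_folds = 5,
                      k_select = 5, repetitions = 2, seed = 11,
                      perturb_test = function(X) {
                        matrix(rnorm(length(X), sd = 50), nrow(X))
                      })
  expect_identical(noised$selected_features, base$selected_features)
  expect_identical(noised$fold_params, base$fold_params)
  expect_false(isTRUE(all.equal(noised$per_repetition$auroc,
                                base$per_repetition$auroc)))
})

test_that("aggregate half-widths shrink with more repetitions", {
  fm <- make_random_fm(n_pos = 12, n_neg = 12, n_features = 10,
                       informative = 2, delta = 0.8, seed = 54)
  rep <- nested_cv(fm, classifier_spec("logistic_regression",
                                       grid = data.frame(lambda = 0.1)),
                   outer_folds = 6, k_select = 4, repetitions = 40, seed = 12)
  auc <- rep$per_repetition$auroc
  hw10 <- sd(auc[1:10]) / sqrt(10)
  hw40 <- sd(auc) / sqrt(40)
  expect_lt(hw40, hw10)
  expect_equal(rep$aggregate$half_width[rep$aggregate$metric == "auroc"],
               hw40)
  expect_true(all(rep$per_repetition$auroc >= 0 & rep$per_repetition$auroc <= 1))
})

test_that("stratification and selection preconditions are enforced", {
  fm <- make_random_fm(n_pos = 4, n_neg = 12, n_features = 6, seed = 55)
  expect_error(nested_cv(fm, classifier_spec("naive_bayes"),
                         outer_folds = 10, k_select = 3, repetitions = 1),
               "per outer fold")
  expect_error(nested_cv(make_random_fm(seed = 56), classifier_spec("knn"),
                         outer_folds = 5, k_select = 99, repetitions = 1),
               "exceeds")
})

test_that("every classifier family runs through nested CV", {
  fm <- make_random_fm(n_pos = 10, n_neg = 10, n_features = 8,
                       informative = 3, delta = 1.5, seed = 57)
  for (clf in c("logistic_regression", "svm", "decision_tree",
                "naive_bayes", "knn", "random_forest")) {
    rep <- nested_cv(fm, classifier_spec(clf), outer_folds = 4,
                     k_select = 3, repetitions = 1, seed = 13)
    m <- rep$per_repetition
    expect_true(all(is.finite(c(m$auroc, m$sensitivity, m$specificity,
                                m$accuracy))), info = clf)
    expect_true(m$auroc >= 0 && m$auroc <= 1, info = clf)
  }
})
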