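test_that("Mann-Whitney U on fully separated small samples is exact", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)   # 2/20 assignments as extreme
  expect_identical(res$method, "exact")
})

test_that("U statistic symmetry and complement identities hold", {
  x <- c(2, 4, 6, 8)
  res <- mann_whitney_u(x, x)
  expect_equal(res$U, length(x)^2 / 2)

  set.seed(41)
  for (case in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    ua <- mann_whitney_u(a, b)$U
    ub <- mann_whitney_u(b, a)$U
    expect_equal(ua + ub, length(a) * length(b))
  }
})

test_that("exact p-values agree with the reference exact distribution", {
  set.seed(42)
  for (case in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    mine <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_identical(mine$method, "exact")
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the normal approximation with tie and continuity correction matches", {
  set.seed(43)
  for (case in 1:6) {
    x <- round(rnorm(15), 1); y <- round(rnorm(12), 1)  # forced ties
    mine <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_identical(mine$method, "normal")
    expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(44)
  x <- runif(9, 1, 5); y <- runif(7, 1, 5)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(exp(x), exp(y))
  expect_equal(a$U, b$U)
  expect_equal(a$p, b$p)
})

test_that("the two-group ANOVA F matches hand arithmetic and t-squared", {
  expect_equal(anova_f(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$F, 0)

  res <- anova_f(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 13.5)   # SSB 13.5, MSW 1
  expect_equal(res$p, pf(13.5, 1, 4, lower.tail = FALSE))

  set.seed(45)
  v <- rnorm(20); g <- rep(c("a", "b"), 10)
  f <- anova_f(v, g)
  tt <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(f$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(f$p, tt$p.value, tolerance = 1e-10)
  ow <- oneway.test(v ~ g, var.equal = TRUE)
  expect_equal(f$F, unname(ow$statistic), tolerance = 1e-10)

  expect_equal(anova_f(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               list(F = Inf, p = 0))
})

test_that("feature ranking sorts by p-value and is row-order stable", {
  fm <- make_random_fm(n_pos = 12, n_neg = 10, n_features = 8, seed = 46)
  fm$perfect <- as.numeric(fm$group == "ADHD")
  class(fm) <- c("feature_matrix", "data.frame")
  rk <- rank_features(fm, method = "anova_f")
  expect_identical(rk$feature[1], "perfect")
  expect_true(!is.unsorted(rk$p_value))

  perm <- sample(nrow(fm))
  fmp <- fm[perm, ]
  class(fmp) <- c("feature_matrix", "data.frame")
  expect_equal(as.data.frame(rank_features(fmp, method = "anova_f")),
               as.data.frame(rk))

  # constant columns fall to the bottom with p = 1
  fm$flat <- 1
  class(fm) <- c("feature_matrix", "data.frame")
  rk2 <- rank_features(fm)
  expect_equal(rk2$p_value[rk2$feature == "flat"], 1)
})

test_that("ANOVA-F ranking order equals absolute-t ranking order", {
  fm <- make_random_fm(n_pos = 11, n_neg = 9, n_features = 15,
                       informative = 4, delta = 1, seed = 47)
  rk <- rank_features(fm, method = "anova_f")
  tstats <- vapply(feature_names(fm), function(f) {
    v <- fm[[f]]
    abs(t.test(v[fm$group == "ADHD"], v[fm$group == "CTRL"],
               var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_identical(rk$feature,
                   names(sort(tstats, decreasing = TRUE)))
})

test_that("label-independent features give approximately uniform p-values", {
  fm <- make_random_fm(n_pos = 28, n_neg = 22, n_features = 100, seed = 48)
  rk <- rank_features(fm, method = "mann_whitney")
  ks <- suppressWarnings(ks.test(rk$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.15)
})

test_that("top-k selection returns rank-ordered names and guards k", {
  fm <- strong_fm()
  rk <- rank_features(fm)
  expect_length(select_top_k(rk, 9), 9)
  expect_identical(select_top_k(rk, 9), rk$feature[1:9])
  expect_true(max(rk$p_value[rk$feature %in% select_top_k(rk, 15)]) <=
                min(rk$p_value[!rk$feature %in% select_top_k(rk, 15)]))
  expect_length(select_top_k(rk, nrow(rk)), nrow(rk))
  expect_error(select_top_k(rk, 0), "at least 1")
  expect_error(select_top_k(rk, nrow(rk) + 1), "exceeds")
})
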