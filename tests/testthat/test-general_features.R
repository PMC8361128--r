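test_that("absolute energy is the sum of squares", {
  expect_equal(absolute_energy(c(1, 2, 3)), 14)
  expect_equal(absolute_energy(rep(0, 10)), 0)
  set.seed(31)
  x <- rnorm(100, 2)
  expect_equal(absolute_energy(x), oracle_energy(x), tolerance = 1e-12)
  k <- 2.5
  expect_equal(absolute_energy(k * x), k^2 * absolute_energy(x))
  expect_error(absolute_energy(numeric()), "empty")
})

test_that("FFT real coefficients match the naive DFT", {
  expect_equal(fft_real_coefficient(c(1, 0, -1, 0), 1), 2.0)
  expect_equal(fft_real_coefficient(rep(3, 8), 0), 24)
  expect_equal(fft_real_coefficient(rep(3, 8), 3), 0, tolerance = 1e-12)

  set.seed(32)
  x <- rnorm(64)
  for (k in c(0, 1, 2, 5, 31, 63)) {
    expect_equal(fft_real_coefficient(x, k), oracle_dft_real(x, k),
                 tolerance = 1e-9)
  }
  # linearity
  y <- rnorm(64)
  expect_equal(fft_real_coefficient(2 * x + 3 * y, 2),
               2 * fft_real_coefficient(x, 2) + 3 * fft_real_coefficient(y, 2))
  expect_error(fft_real_coefficient(x, 64), "out of range")
  expect_error(fft_real_coefficient(x, -1), "out of range")
})

test_that("change-quantile variance follows the corridor definition", {
  expect_equal(change_quantiles_var(rep(5, 20)), 0)
  # corridor [q0.4, q0.8] of c(0, 100) contains neither point
  expect_equal(change_quantiles_var(c(0, 100)), 0)

  set.seed(33)
  for (case in 1:5) {
    x <- rnorm(200)
    expect_equal(change_quantiles_var(x),
                 oracle_change_quantiles(x, 0.4, 0.8), tolerance = 1e-12)
  }
  x <- cumsum(rnorm(150))
  expect_equal(change_quantiles_var(x, 0.2, 0.9),
               oracle_change_quantiles(x, 0.2, 0.9), tolerance = 1e-12)
  expect_error(change_quantiles_var(x, 0.8, 0.4), "ql < qh")
})

test_that("approximate entropy matches a literal Pincus implementation", {
  expect_equal(approximate_entropy(rep(1, 50)), 0)

  alternating <- rep(c(0, 1), 50)
  set.seed(34)
  noisy <- runif(100)
  expect_lt(approximate_entropy(alternating), approximate_entropy(noisy))

  x <- rnorm(120)
  r <- 0.2 * sqrt(mean((x - mean(x))^2))
  expect_equal(approximate_entropy(x, m = 2, r_factor = 0.2),
               oracle_apen(x, 2, r), tolerance = 1e-9)
  expect_error(approximate_entropy(c(1, 2, 3), m = 2), "too short")
})

test_that("approximate entropy is shift-invariant and scale-invariant with r scaling", {
  set.seed(35)
  x <- rnorm(150)
  expect_equal(approximate_entropy(x + 100), approximate_entropy(x),
               tolerance = 1e-12)
  # r = r_factor * sd scales with the data, so positive rescaling cancels
  expect_equal(approximate_entropy(3 * x), approximate_entropy(x),
               tolerance = 1e-10)
})

test_that("peak counting matches brute force and its conventions", {
  expect_equal(number_peaks(as.numeric(1:50), 10), 0)

  bump <- c(rep(0, 12), 0.5, 1, 0.5, rep(0, 12))
  expect_equal(number_peaks(bump, 10), 1)

  set.seed(36)
  x <- rnorm(300)
  expect_equal(number_peaks(x, 10), oracle_peaks(x, 10))
  expect_equal(number_peaks(x, 3), oracle_peaks(x, 3))
  expect_equal(number_peaks(x + 42, 10), number_peaks(x, 10))

  expect_warning(out <- number_peaks(rnorm(15), 10), "too short")
  expect_equal(out, 0L)
})

test_that("linear-trend slope standard error matches closed-form OLS", {
  expect_equal(linear_trend_stderr(2 + 0.3 * (0:19)), 0, tolerance = 1e-12)
  expect_equal(linear_trend_stderr(rep(4, 10)), 0)
  expect_equal(linear_trend_stderr(c(0, 1, 0)), sqrt(1 / 3), tolerance = 1e-12)

  set.seed(37)
  x <- rnorm(80)
  fit <- lm(x ~ I(0:79))
  expect_equal(linear_trend_stderr(x),
               summary(fit)$coefficients[2, 2], tolerance = 1e-10)
  expect_error(linear_trend_stderr(c(1, 2)), "at least 3")
})

test_that("basic moments use population conventions", {
  m <- basic_moments(c(1, 2, 3))
  expect_equal(m$mean, 2)
  expect_equal(m$median, 2)
  expect_equal(m$variance, 2 / 3)
  expect_equal(m$std, sqrt(2 / 3))

  const <- basic_moments(rep(7, 5))
  expect_equal(const$variance, 0)
  expect_equal(const$skew, 0)
  expect_equal(const$kurtosis, 0)

  set.seed(38)
  x <- rexp(200)
  mm <- basic_moments(x)
  n <- length(x); mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n; m3 <- sum((x - mu)^3) / n; m4 <- sum((x - mu)^4) / n
  expect_equal(mm$variance, m2)
  expect_equal(mm$skew, m3 / m2^1.5)
  expect_equal(mm$kurtosis, m4 / m2^2 - 3)
})

test_that("every registry feature is finite on generic trials", {
  reg <- general_feature_registry()
  expect_identical(names(reg), list_general_features())
  expect_length(reg, 12)
  set.seed(39)
  for (case in 1:5) {
    tr <- make_trial(rnorm(64, 3), period_ms = 16)
    vals <- vapply(reg, function(s) s$compute(tr), numeric(1))
    expect_true(all(is.finite(vals)))
  }
})

test_that("the feature matrix averages per-trial values by subject", {
  tr <- make_trial(sin((0:499) / 20) + 3, period_ms = 16)
  same_twice <- pupil_cohort(list(
    list(subject_id = "a", group = "ADHD",
         trials = list(tr, make_trial(tr$pupil, period_ms = 16, trial = "t2"))),
    list(subject_id = "b", group = "CTRL",
         trials = list(make_trial(cos((0:499) / 15) + 3, period_ms = 16)))))
  fm <- build_feature_matrix(same_twice)
  expect_equal(dim(feature_values(fm)), c(2L, 34L))
  expect_identical(feature_names(fm),
                   c(list_custom_features(), list_general_features()))

  # subject with two identical trials: per-subject value == per-trial value
  single <- extract_custom_features(tr)
  expect_equal(unname(feature_values(fm)["a", list_custom_features()]),
               unname(single))

  # two-stage oracle for absolute energy on a small synthetic cohort
  gen <- generate_cohort(scaled_config("null", 7, n_adhd = 2, n_ctrl = 2,
                                       trials = 3))
  pp <- preprocess_cohort(gen$cohort)
  fm2 <- build_feature_matrix(pp$cohort)
  for (si in seq_along(pp$cohort$subjects)) {
    s <- pp$cohort$subjects[[si]]
    manual <- mean(vapply(s$trials,
                          function(tr) oracle_energy(tr$pupil), numeric(1)))
    expect_equal(feature_values(fm2)[s$subject_id, "absolute_energy"],
                 manual, tolerance = 1e-10, ignore_attr = TRUE)
  }
})
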