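test_that("dilation velocity is the secant slope from the origin", {
  tr <- make_trial(c(2.0, 2.5), period_ms = 250)
  v <- dilation_velocity(tr, 0L)
  expect_equal(v, c(0, 0.002))

  const <- make_trial(rep(3, 50))
  expect_equal(dilation_velocity(const, 0L), rep(0, 50))

  m <- 0.025
  lin <- make_trial(1 + m * (0:99) * 4, period_ms = 4)
  expect_equal(dilation_velocity(lin, 0L)[-1], rep(m, 99))
})

test_that("acceleration is zero on linear series and matches the formula on quadratics", {
  lin <- make_trial(2 + 0.01 * (0:49), period_ms = 1)
  expect_equal(dilation_acceleration(lin, 0L), rep(0, 50))

  cc <- 3e-4
  t <- 0:99
  quad <- make_trial(cc * t^2, period_ms = 1)
  a <- dilation_acceleration(quad, 0L)
  # from the origin at T0 = 0: V_i = c*T_i, V_0 (first post-origin) = c*T_1,
  # so A_i = c*(T_i - T_1)/(T_i - T_0)
  expected <- c(0, 0, cc * (t[-(1:2)] - t[2]) / t[-(1:2)])
  expect_equal(a, expected)
})

test_that("velocity is shift-invariant and all dilation series scale linearly", {
  set.seed(21)
  x <- cumsum(rnorm(200))
  tr <- make_trial(x, period_ms = 2)
  shifted <- make_trial(x + 7.5, period_ms = 2)
  expect_equal(dilation_velocity(shifted, 0L), dilation_velocity(tr, 0L))

  k <- 3.5
  scaled <- make_trial(k * x, period_ms = 2)
  s1 <- dilation_series(tr, 5L)
  s2 <- dilation_series(scaled, 5L)
  expect_equal(s2$v, k * s1$v)
  expect_equal(s2$a, k * s1$a)
  expect_equal(s2$av, k * s1$av)
})

test_that("accumulated velocity is the prefix sum of velocity", {
  set.seed(22)
  tr <- make_trial(rnorm(100), period_ms = 4)
  s <- dilation_series(tr, 0L)
  expect_equal(diff(s$av), s$v[-1])
  expect_equal(s$av[1], s$v[1])
})

test_that("the custom extractor returns the full 22-feature catalogue", {
  set.seed(23)
  tr <- make_trial(rnorm(500, 3), period_ms = 16)
  f <- extract_custom_features(tr)
  expect_length(f, 22)
  expect_identical(names(f), list_custom_features())
  expect_true(all(is.finite(f)))
})

test_that("a constant trial yields the documented degenerate values", {
  tr <- make_trial(rep(2.5, 500), period_ms = 16)
  f <- extract_custom_features(tr)
  expect_equal(unname(f[c(1, 2, 4, 8, 9)]), rep(2.5, 5))
  expect_equal(unname(f[3]), 2.5)
  expect_equal(unname(f[c(5, 6, 7, 10:22)]), rep(0, 16))
})

test_that("item 19 follows the configured interpretation", {
  set.seed(24)
  tr <- make_trial(rnorm(500, 3), period_ms = 16)
  lit <- extract_custom_features(tr, item19 = "literal")
  expect_equal(lit[["velocity_accum_contrast"]],
               lit[["max_velocity_after_minus_max_accum_before"]])
  alt <- extract_custom_features(tr, item19 = "velocity_contrast")
  expect_equal(alt[["velocity_accum_contrast"]],
               alt[["max_velocity_after_probe"]] -
                 alt[["max_accum_velocity_after_probe"]])
})

test_that("windowed features on a piecewise trial match direct evaluation", {
  t <- (0:499) * 16
  p <- ifelse(t < 5000, 2.0, ifelse(t < 7000, 2 + (t - 5000) / 2000, 3.0))
  tr <- make_trial(p, period_ms = 16)
  f <- extract_custom_features(tr)

  expect_equal(f[["mean_velocity_before_probe"]], 0)
  expect_equal(f[["max_velocity_before_probe"]], 0)
  # windows are half-open ms intervals mapped to samples by floor division
  win1 <- seq.int(floor(5000 / 16) + 1, floor(7000 / 16))
  expect_equal(f[["max_size_5000_7000"]], max(p[win1]))
  expect_gt(f[["mean_velocity_after_probe"]], 0)

  # brute-force secant-slope evaluation over the post-probe samples,
  # origin re-anchored at the probe sample (floor(5000 / 16), 0-based)
  probe_i <- floor(5000 / 16) + 1
  vs <- c()
  for (i in seq(probe_i + 1, length(p))) {
    vs <- c(vs, (p[i] - p[probe_i]) / (t[i] - t[probe_i]))
  }
  expect_equal(f[["mean_velocity_after_probe"]], mean(vs))
  expect_equal(f[["max_velocity_after_probe"]], max(vs))
  expect_equal(f[["max_accum_velocity_after_probe"]], max(cumsum(vs)))
})

test_that("feature scaling behaviour separates location, scale and shape items", {
  set.seed(25)
  x <- 3 + cumsum(rnorm(500, sd = 0.05))
  k <- 4
  f1 <- extract_custom_features(make_trial(x, period_ms = 16))
  fk <- extract_custom_features(make_trial(k * x, period_ms = 16))
  scale_items <- setdiff(list_custom_features(),
                         c("size_kurtosis", "size_skew"))
  expect_equal(unname(fk[scale_items]), unname(k * f1[scale_items]))
  expect_equal(fk[["size_skew"]], f1[["size_skew"]])
  expect_equal(fk[["size_kurtosis"]], f1[["size_kurtosis"]])
})

test_that("before- and after-probe windows partition the trial", {
  tr <- make_trial(rnorm(500), period_ms = 16)
  probe_i <- floor(5000 / 16)            # 0-based probe sample
  before <- seq.int(0, probe_i - 1)
  after <- seq.int(probe_i, 499)
  expect_length(intersect(before, after), 0)
  expect_equal(sort(c(before, after)), 0:499)
})

test_that("trials that cannot satisfy the windows are rejected", {
  short <- make_trial(rnorm(100), period_ms = 16)   # spans only 1600 ms
  expect_error(extract_custom_features(short), "too short")
  offset <- pupil_trial("s", "t", 100 + (0:499) * 16, rnorm(500))
  expect_error(extract_custom_features(offset), "t = 0")
})
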