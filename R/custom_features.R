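#' Probe timing of a task trial
#'
#' Trials are stimulus-locked: a probe appears `probe_ms` into the trial
#' (5000 ms in the visuospatial working-memory task) and the trial ends at
#' `trial_end_ms` (8000 ms). All "before"/"after" feature windows are
#' defined relative to these marks.
#'
#' @param probe_ms Probe presentation time in ms (default 5000).
#' @param trial_end_ms Trial end in ms (default 8000).
#' @return A `probe_timing` object.
#' @export
probe_timing <- function(probe_ms = 5000, trial_end_ms = 8000) {
  if (!(probe_ms > 0 && probe_ms < trial_end_ms)) {
    stop("need 0 < probe_ms < trial_end_ms", call. = FALSE)
  }
  structure(list(probe_ms = probe_ms, trial_end_ms = trial_end_ms),
            class = "probe_timing")
}

#' Pupil-size dilation velocity from a fixed origin
#'
#' The dilation velocity at sample i is the secant slope from the origin
#' sample: `V_i = (P_i - P_0) / (T_i - T_0)`, in pupil units per ms. The
#' velocity at the origin itself is undefined and stored as 0 by convention.
#'
#' @param trial A fully observed [pupil_trial()].
#' @param origin_index 0-based index of the origin sample (T_0, P_0).
#' @return Numeric vector of velocities for samples `origin_index` to the
#'   end of the trial (first element 0).
#' @export
dilation_velocity <- function(trial, origin_index = 0L) {
  stopifnot(inherits(trial, "pupil_trial"))
  if (anyNA(trial$pupil)) stop("trial must be fully observed", call. = FALSE)
  n <- length(trial$pupil)
  o <- as.integer(origin_index) + 1L
  if (o < 1L || o > n) stop("origin_index out of range", call. = FALSE)
  idx <- seq.int(o, n)
  v <- (trial$pupil[idx] - trial$pupil[o]) / (trial$t_ms[idx] - trial$t_ms[o])
  v[1] <- 0
  v
}

#' Pupil-size dilation acceleration from a fixed origin
#'
#' `A_i = (V_i - V_0) / (T_i - T_0)`, where `V_0` is the velocity at the
#' first sample after the origin (the first index at which the secant
#' velocity is defined). The values at the origin and at that first sample
#' are 0 by convention/identity.
#'
#' @inheritParams dilation_velocity
#' @return Numeric vector of accelerations, aligned with
#'   [dilation_velocity()].
#' @export
dilation_acceleration <- function(trial, origin_index = 0L) {
  v <- dilation_velocity(trial, origin_index)
  if (length(v) < 3) {
    stop("acceleration needs at least 3 samples from the origin", call. = FALSE)
  }
  o <- as.integer(origin_index) + 1L
  idx <- seq.int(o, length(trial$pupil))
  dt <- trial$t_ms[idx] - trial$t_ms[o]
  a <- (v - v[2]) / dt
  a[1] <- 0
  a
}

#' Velocity, acceleration and accumulated velocity from an origin
#'
#' Bundles [dilation_velocity()], [dilation_acceleration()] and the
#' accumulated velocity (the running prefix sum `AV_i = V_0 + ... + V_i`).
#'
#' @inheritParams dilation_velocity
#' @return A list with numeric vectors `v`, `a`, `av` (all aligned, starting
#'   at the origin) and `origin_index`.
#' @export
dilation_series <- function(trial, origin_index = 0L) {
  v <- dilation_velocity(trial, origin_index)
  a <- dilation_acceleration(trial, origin_index)
  list(v = v, a = a, av = cumsum(v), origin_index = as.integer(origin_index))
}

#' Names of the 22 custom pupillometric features
#'
#' Stable catalogue order; [extract_custom_features()] returns exactly these
#' names in this order.
#'
#' @return Character vector of length 22.
#' @export
list_custom_features <- function() {
  c("max_size_5000_7000",            # 1
    "max_size_1_5000",               # 2
    "min_size_6500_8000",            # 3
    "mean_size_5500_7000",           # 4
    "size_std",                      # 5
    "size_kurtosis",                 # 6
    "size_skew",                     # 7
    "size_median",                   # 8
    "size_mean",                     # 9
    "mean_velocity_before_probe",    # 10
    "mean_velocity_after_probe",     # 11
    "max_velocity_before_probe",     # 12
    "max_velocity_after_probe",      # 13
    "max_accum_velocity_before_probe",  # 14
    "max_accum_velocity_after_probe",   # 15
    "accum_velocity_after_minus_before",         # 16
    "max_velocity_after_minus_max_accum_before", # 17
    "mean_velocity_after_minus_max_accum_before",# 18
    "velocity_accum_contrast",       # 19 (see ?extract_custom_features)
    "max_acceleration_5000_7000",    # 20
    "min_acceleration_5000_7000",    # 21
    "mean_acceleration_5000_7000")   # 22
}

# population moments shared by custom and general features;
# skew/kurtosis of a constant series are 0 by convention
moments_pop <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    return(list(mean = m, median = stats::median(x), var = 0, sd = 0,
                skew = 0, kurtosis = 0))
  }
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  list(mean = m, median = stats::median(x), var = m2, sd = sqrt(m2),
       skew = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

#' Extract the 22 custom pupillometric features from one trial
#'
#' Implements the per-trial custom catalogue built on the dilation metrics:
#' windowed extremes and means of pupil size, whole-trial moments, and
#' velocity / accumulated-velocity / acceleration summaries split at the
#' probe. "Before probe" quantities anchor the velocity origin at the trial
#' start; "after probe" quantities re-anchor it at the probe sample, so they
#' measure the stimulus-locked response. Windows are millisecond half-open
#' intervals `[T1, T2)` mapped to samples by floor division.
#'
#' Item 19 of the catalogue as printed duplicates item 17
#' (`max_velocity_after - max_accum_velocity_before`); `item19 = "literal"`
#' (default) keeps the duplicate, `item19 = "velocity_contrast"` substitutes
#' the alternative reading `max_velocity_after - max_accum_velocity_after`.
#'
#' @param trial A fully observed, reduced [pupil_trial()] spanning
#'   `[0, trial_end_ms)`.
#' @param timing A [probe_timing()].
#' @param item19 Interpretation switch for item 19 (see Details).
#' @return Named numeric vector of length 22, in [list_custom_features()]
#'   order.
#' @export
extract_custom_features <- function(trial, timing = probe_timing(),
                                    item19 = c("literal", "velocity_contrast")) {
  stopifnot(inherits(trial, "pupil_trial"), inherits(timing, "probe_timing"))
  item19 <- match.arg(item19)
  if (anyNA(trial$pupil)) stop("trial must be fully observed", call. = FALSE)
  n <- length(trial$pupil)
  period <- trial$sample_period_ms
  if (trial$t_ms[1] != 0) {
    stop("trial must start at t = 0 ms", call. = FALSE)
  }
  if (trial$t_ms[n] + period < timing$trial_end_ms) {
    stop(sprintf("trial too short for window [%g, %g) ms",
                 timing$probe_ms, timing$trial_end_ms), call. = FALSE)
  }
  p <- trial$pupil
  probe_i <- ms_to_index(timing$probe_ms, period)   # 0-based probe sample

  win <- function(a, b) p[window_indices(trial, a, b)]
  mom <- moments_pop(p)

  # velocities anchored at trial start, restricted to samples before probe
  v_pre_all <- dilation_velocity(trial, 0L)          # index 0..n-1
  pre_idx <- seq.int(2L, probe_i)                    # 0-based 1..probe-1
  v_pre <- v_pre_all[pre_idx]
  av_pre <- cumsum(v_pre)

  # velocities re-anchored at the probe sample
  v_post_all <- dilation_velocity(trial, probe_i)    # index probe..n-1
  v_post <- v_post_all[-1]
  av_post <- cumsum(v_post)

  # acceleration anchored at the probe, over the [5000, 7000) ms window
  a_post <- dilation_acceleration(trial, probe_i)
  post0 <- probe_i + seq_along(a_post) - 1L          # 0-based indices
  w_lo <- ms_to_index(timing$probe_ms, period)
  w_hi <- ms_to_index(timing$probe_ms + 2000, period)
  a_win <- a_post[post0 > probe_i & post0 >= w_lo & post0 < w_hi]

  out <- c(
    max(win(timing$probe_ms, timing$probe_ms + 2000)),    # 1
    max(win(1, timing$probe_ms)),                         # 2
    min(win(timing$trial_end_ms - 1500, timing$trial_end_ms)),  # 3
    mean(win(timing$probe_ms + 500, timing$probe_ms + 2000)),   # 4
    mom$sd, mom$kurtosis, mom$skew, mom$median, mom$mean, # 5-9
    mean(v_pre),                                          # 10
    mean(v_post),                                         # 11
    max(v_pre),                                           # 12
    max(v_post),                                          # 13
    max(av_pre),                                          # 14
    max(av_post),                                         # 15
    max(av_post) - max(av_pre),                           # 16
    max(v_post) - max(av_pre),                            # 17
    mean(v_post) - max(av_pre),                           # 18
    if (item19 == "literal") max(v_post) - max(av_pre) else
      max(v_post) - max(av_post),                         # 19
    max(a_win), min(a_win), mean(a_win))                  # 20-22
  names(out) <- list_custom_features()
  out
}
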