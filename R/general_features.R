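#' Absolute energy of a series
#'
#' Sum of squared sample values, `sum(x^2)`.
#'
#' @param x Numeric vector, non-empty, fully observed.
#' @return A number.
#' @export
absolute_energy <- function(x) {
  if (!length(x)) stop("empty series", call. = FALSE)
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  sum(x^2)
}

#' Real part of one discrete Fourier coefficient
#'
#' `Re(X_k)` with `X_k = sum_n x_n exp(-2*pi*i*k*n/N)` (unnormalized DFT,
#' 0-based `k`).
#'
#' @param x Numeric vector.
#' @param k Coefficient index, `0 <= k < length(x)` (default 2, the
#'   discriminative coefficient of the screening study).
#' @return A number.
#' @export
fft_real_coefficient <- function(x, k = 2L) {
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  k <- as.integer(k)
  if (k < 0L || k >= length(x)) {
    stop(sprintf("coefficient index k = %d out of range [0, %d)", k, length(x)),
         call. = FALSE)
  }
  Re(stats::fft(x)[k + 1L])
}

#' Variance of absolute consecutive changes inside a quantile corridor
#'
#' The corridor is `[quantile(x, ql), quantile(x, qh)]` (linear-interpolation
#' sample quantiles, endpoints inclusive). For every consecutive pair with
#' BOTH endpoints inside the corridor, the change `|x[i+1] - x[i]|` (or the
#' signed change when `absolute = FALSE`) is collected; the population
#' variance of the collected changes is returned, 0 when fewer than 2 pairs
#' qualify.
#'
#' @param x Numeric vector, length >= 2.
#' @param ql,qh Corridor quantiles, `0 <= ql < qh <= 1` (defaults 0.4, 0.8).
#' @param absolute Use absolute changes (default TRUE).
#' @return A number >= 0.
#' @export
change_quantiles_var <- function(x, ql = 0.4, qh = 0.8, absolute = TRUE) {
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!(ql >= 0 && ql < qh && qh <= 1)) {
    stop("need 0 <= ql < qh <= 1", call. = FALSE)
  }
  lo <- stats::quantile(x, ql, names = FALSE, type = 7)
  hi <- stats::quantile(x, qh, names = FALSE, type = 7)
  inside <- x >= lo & x <= hi
  ok <- inside[-length(x)] & inside[-1]
  if (sum(ok) < 2) return(0)
  d <- diff(x)[ok]
  if (absolute) d <- abs(d)
  mean((d - mean(d))^2)
}

#' Approximate entropy (Pincus ApEn)
#'
#' Regularity statistic: low for predictable series, high for erratic ones.
#' `ApEn(m, r) = Phi_m - Phi_{m+1}`, where
#' `Phi_m = (N - m + 1)^{-1} * sum_i log(C_i^m)` and `C_i^m` is the fraction
#' of length-`m` template vectors (self-match included) within Chebyshev
#' distance `r` of template `i`. The tolerance is `r = r_factor * sd(x)`
#' (population sd). A constant series returns 0.
#'
#' @param x Numeric vector with `length(x) > m + 1`.
#' @param m Embedding (template) length, default 2.
#' @param r_factor Tolerance as a multiple of the series sd, default 0.2.
#' @return A number >= 0 (up to floating-point noise).
#' @export
approximate_entropy <- function(x, m = 2L, r_factor = 0.2) {
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  m <- as.integer(m)
  n <- length(x)
  if (n <= m + 1L) stop("series too short for the embedding length", call. = FALSE)
  sdev <- sqrt(mean((x - mean(x))^2))
  if (sdev == 0) return(0)
  r <- r_factor * sdev
  phi <- function(mm) {
    nt <- n - mm + 1L
    # Chebyshev distance between templates, accumulated one lag at a time
    dmax <- matrix(0, nt, nt)
    for (k in seq_len(mm)) {
      xs <- x[seq.int(k, k + nt - 1L)]
      dmax <- pmax(dmax, abs(outer(xs, xs, "-")))
    }
    cts <- rowSums(dmax <= r) / nt
    mean(log(cts))
  }
  phi(m) - phi(m + 1L)
}

#' Count peaks with n-sample support
#'
#' A sample is a peak when it is strictly greater than all `n` neighbours on
#' each side; only indices with full support on both sides are eligible.
#'
#' @param x Numeric vector.
#' @param n Neighbourhood half-width, default 10.
#' @return Integer count (0 with a warning when `length(x) <= 2n`).
#' @export
number_peaks <- function(x, n = 10L) {
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  n <- as.integer(n)
  N <- length(x)
  if (N <= 2L * n) {
    warning(sprintf("series of length %d too short for peak support %d; 0 peaks",
                    N, n))
    return(0L)
  }
  cand <- seq.int(n + 1L, N - n)   # 1-based; 0-based n .. N-n-1
  is_peak <- rep(TRUE, length(cand))
  for (lag in seq_len(n)) {
    is_peak <- is_peak & x[cand] > x[cand - lag] & x[cand] > x[cand + lag]
  }
  sum(is_peak)
}

#' Standard error of the linear-trend slope
#'
#' OLS of `x` on the sample index `0..N-1`:
#' `sqrt((SSE / (N - 2)) / sum((i - mean(i))^2))`.
#'
#' @param x Numeric vector, length >= 3.
#' @return A number >= 0.
#' @export
linear_trend_stderr <- function(x) {
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  N <- length(x)
  if (N < 3) stop("need at least 3 samples", call. = FALSE)
  i <- seq_len(N) - 1
  sxx <- sum((i - mean(i))^2)
  slope <- sum((i - mean(i)) * (x - mean(x))) / sxx
  fitted <- mean(x) + slope * (i - mean(i))
  sse <- sum((x - fitted)^2)
  sqrt((sse / (N - 2)) / sxx)
}

#' Basic moments of a series
#'
#' Population variants throughout: variance `mean((x - mean)^2)`, skew the
#' standardized third moment, kurtosis excess (Fisher) without bias
#' correction. Skew and kurtosis of a constant series are 0 by convention.
#' Conventions are shared with the custom catalogue (items 5-9).
#'
#' @param x Numeric vector, non-empty.
#' @return Named list: `mean`, `median`, `variance`, `std`, `skew`,
#'   `kurtosis`.
#' @export
basic_moments <- function(x) {
  if (!length(x)) stop("empty series", call. = FALSE)
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  m <- moments_pop(x)
  list(mean = m$mean, median = m$median, variance = m$var, std = m$sd,
       skew = m$skew, kurtosis = m$kurtosis)
}

#' Default registry of general time-series features
#'
#' The discriminative general features of the screening study (absolute
#' energy, real FFT coefficient 2, change-quantile variance over the
#' 0.4-0.8 corridor, approximate entropy at m = 2, peak count at n = 10,
#' linear-trend slope standard error) plus the six basic moments. Each
#' entry is a `FeatureSpec`: a name, its parameters, and a pure function
#' from a trial to one finite number.
#'
#' @param fft_k FFT coefficient index (default 2).
#' @param ql,qh Change-quantile corridor (defaults 0.4, 0.8).
#' @param apen_m,apen_r_factor Approximate-entropy embedding length and
#'   tolerance factor (defaults 2, 0.2).
#' @param peaks_n Peak support (default 10).
#' @return Named list of feature specs, each
#'   `list(name, params, compute = function(trial) number)`.
#' @export
general_feature_registry <- function(fft_k = 2L, ql = 0.4, qh = 0.8,
                                     apen_m = 2L, apen_r_factor = 0.2,
                                     peaks_n = 10L) {
  spec <- function(name, params, fn) list(name = name, params = params, compute = fn)
  specs <- list(
    spec("absolute_energy", list(),
         function(tr) absolute_energy(tr$pupil)),
    spec("fft_coefficient_real", list(k = fft_k),
         function(tr) fft_real_coefficient(tr$pupil, k = fft_k)),
    spec("change_quantiles_var", list(ql = ql, qh = qh, absolute = TRUE),
         function(tr) change_quantiles_var(tr$pupil, ql = ql, qh = qh)),
    spec("approximate_entropy", list(m = apen_m, r_factor = apen_r_factor),
         function(tr) approximate_entropy(tr$pupil, m = apen_m,
                                          r_factor = apen_r_factor)),
    spec("number_peaks", list(n = peaks_n),
         function(tr) number_peaks(tr$pupil, n = peaks_n)),
    spec("linear_trend_stderr", list(),
         function(tr) linear_trend_stderr(tr$pupil)),
    spec("ts_mean", list(), function(tr) mean(tr$pupil)),
    spec("ts_median", list(), function(tr) stats::median(tr$pupil)),
    spec("ts_variance", list(), function(tr) basic_moments(tr$pupil)$variance),
    spec("ts_std", list(), function(tr) basic_moments(tr$pupil)$std),
    spec("ts_skew", list(), function(tr) basic_moments(tr$pupil)$skew),
    spec("ts_kurtosis", list(), function(tr) basic_moments(tr$pupil)$kurtosis)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Names of the default general features
#' @inheritParams general_feature_registry
#' @return Character vector of the 12 default general feature names.
#' @export
list_general_features <- function() {
  names(general_feature_registry())
}

#' Full default feature specification: 22 custom + 12 general
#'
#' @param timing A [probe_timing()] for the custom catalogue.
#' @param item19 Item-19 interpretation, see [extract_custom_features()].
#' @param ... Parameters forwarded to [general_feature_registry()].
#' @return Named list of feature specs (length 34 with defaults).
#' @export
default_feature_specs <- function(timing = probe_timing(),
                                  item19 = "literal", ...) {
  custom_names <- list_custom_features()
  custom <- lapply(seq_along(custom_names), function(j) {
    list(name = custom_names[j], params = list(item = j),
         compute = local({
           jj <- j
           function(tr) extract_custom_features(tr, timing, item19 = item19)[[jj]]
         }))
  })
  names(custom) <- custom_names
  c(custom, general_feature_registry(...))
}

#' Build the subjects-by-features matrix
#'
#' Computes every feature per trial, then aggregates per subject as the
#' arithmetic mean over that subject's kept trials. A spec failing on every
#' trial of a subject is an error naming both; a spec failing on some trials
#' is averaged over the successful ones (count reported via `message`).
#'
#' For the custom catalogue this would evaluate the full 22-vector once per
#' feature; `build_feature_matrix` therefore special-cases it and extracts
#' all 22 custom values in one pass per trial.
#'
#' @param cohort A preprocessed [pupil_cohort()].
#' @param specs Feature specs as from [default_feature_specs()].
#' @param timing A [probe_timing()] (used for the custom-catalogue fast
#'   path; must match the timing the specs were built with).
#' @param item19 Item-19 interpretation for the fast path.
#' @return A `feature_matrix` with one column per spec, in spec order.
#' @export
build_feature_matrix <- function(cohort, specs = default_feature_specs(timing),
                                 timing = probe_timing(), item19 = "literal") {
  stopifnot(inherits(cohort, "pupil_cohort"))
  if (!length(specs)) stop("specs must be non-empty", call. = FALSE)
  spec_names <- vapply(specs, `[[`, character(1), "name")
  custom_set <- list_custom_features()
  is_custom <- spec_names %in% custom_set

  rows <- lapply(cohort$subjects, function(s) {
    per_trial <- matrix(NA_real_, nrow = length(s$trials), ncol = length(specs),
                        dimnames = list(NULL, spec_names))
    for (ti in seq_along(s$trials)) {
      tr <- s$trials[[ti]]
      if (any(is_custom)) {
        cf <- extract_custom_features(tr, timing, item19 = item19)
        per_trial[ti, spec_names[is_custom]] <- cf[spec_names[is_custom]]
      }
      for (j in which(!is_custom)) {
        val <- tryCatch(specs[[j]]$compute(tr), error = function(e) NA_real_)
        per_trial[ti, j] <- val
      }
    }
    vals <- numeric(length(specs))
    for (j in seq_along(specs)) {
      col <- per_trial[, j]
      ok <- is.finite(col)
      if (!any(ok)) {
        stop(sprintf("feature '%s' failed on every trial of subject '%s'",
                     spec_names[j], s$subject_id), call. = FALSE)
      }
      if (!all(ok)) {
        message(sprintf("feature '%s', subject '%s': %d/%d trials usable",
                        spec_names[j], s$subject_id, sum(ok), length(col)))
      }
      vals[j] <- mean(col[ok])
    }
    vals
  })
  values <- do.call(rbind, rows)
  colnames(values) <- spec_names
  feature_matrix(cohort_subject_ids(cohort), cohort_groups(cohort), values)
}
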