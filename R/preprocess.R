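#' Impute missing samples with cubic-spline interpolation
#'
#' Interior gaps (blinks, dropouts) are filled with the cubic spline through
#' the observed `(t_ms, pupil)` points. Leading and trailing missing runs,
#' where a cubic extrapolation would be unstable, are first filled with the
#' nearest observed value; the spline then interpolates only interior gaps.
#' Observed samples pass through unchanged.
#'
#' End conditions are Forsythe–Malcolm–Moler ("fmm": an exact cubic is
#' fitted through the points nearest each end), under which any cubic
#' polynomial is reproduced exactly regardless of gap placement.
#'
#' @param trial A [pupil_trial()].
#' @return A fully observed [pupil_trial()].
#' @export
interpolate_missing <- function(trial) {
  stopifnot(inherits(trial, "pupil_trial"))
  obs <- !is.na(trial$pupil)
  if (sum(obs) < 4) {
    stop(sprintf(
      "trial '%s' of subject '%s' has fewer than 4 observed samples; exclude it",
      trial$trial_id, trial$subject_id), call. = FALSE)
  }
  if (all(obs)) return(trial)

  p <- trial$pupil
  first_obs <- which(obs)[1]
  last_obs <- which(obs)[sum(obs)]
  if (first_obs > 1) p[seq_len(first_obs - 1)] <- p[first_obs]
  if (last_obs < length(p)) p[seq.int(last_obs + 1L, length(p))] <- p[last_obs]

  miss <- is.na(p)
  if (any(miss)) {
    fit <- stats::spline(trial$t_ms[!miss], p[!miss], method = "fmm",
                         xout = trial$t_ms[miss])
    p[miss] <- fit$y
  }
  out <- trial
  out$pupil <- p
  out
}

#' Exclude trials with excessive missingness
#'
#' A trial is dropped when its missing fraction strictly exceeds
#' `max_missing_fraction` ("more than 80% missing" at the default);
#' a trial at exactly the threshold is kept. Missingness is assessed on the
#' raw (pre-imputation) series.
#'
#' @param trials A list of [pupil_trial()] objects.
#' @param max_missing_fraction Exclusion threshold, default 0.8.
#' @return A list with elements `kept` (list of trials) and `dropped`
#'   (character vector of trial ids).
#' @export
exclude_trials <- function(trials, max_missing_fraction = 0.8) {
  if (!length(trials)) return(list(kept = list(), dropped = character()))
  frac <- vapply(trials, function(tr) mean(is.na(tr$pupil)), numeric(1))
  drop <- frac > max_missing_fraction
  list(kept = trials[!drop],
       dropped = vapply(trials[drop], function(tr) tr$trial_id, character(1)))
}

#' Reduce a trial by non-overlapping moving-average blocks
#'
#' Each output sample is the arithmetic mean of one consecutive block of
#' `window_ms / sample_period_ms` input samples; blocks do not overlap, so
#' an 8000-sample 1 kHz trial becomes 500 samples at a 16 ms period. Any
#' trailing remainder shorter than one block is discarded. Output times are
#' the start times of each block.
#'
#' @param trial A fully observed [pupil_trial()].
#' @param window_ms Block width in ms, default 16; must span a whole number
#'   of input samples and at least one.
#' @return A reduced [pupil_trial()] with `sample_period_ms = window_ms`.
#' @export
reduce_series <- function(trial, window_ms = 16) {
  stopifnot(inherits(trial, "pupil_trial"))
  if (anyNA(trial$pupil)) {
    stop("reduce_series requires a fully observed trial; impute first",
         call. = FALSE)
  }
  w_real <- window_ms / trial$sample_period_ms
  w <- round(w_real)
  if (w < 1 || abs(w_real - w) > 1e-9) {
    stop(sprintf(
      "window of %g ms does not span a whole number of %g ms samples",
      window_ms, trial$sample_period_ms), call. = FALSE)
  }
  n_out <- length(trial$pupil) %/% w
  if (n_out < 2) {
    stop("reduction would leave fewer than 2 samples", call. = FALSE)
  }
  keep <- seq_len(n_out * w)
  means <- colMeans(matrix(trial$pupil[keep], nrow = w))
  t_out <- trial$t_ms[seq.int(1L, by = w, length.out = n_out)]
  pupil_trial(trial$subject_id, trial$trial_id, t_out, means,
              sample_period_ms = window_ms)
}

#' Preprocess every trial of a cohort
#'
#' Applies the standard cleaning order per subject: exclusion of trials with
#' more than `max_missing_fraction` missing (assessed before imputation),
#' cubic-spline imputation of the rest, then moving-average reduction.
#' Subjects left with no trials are an error.
#'
#' @param cohort A [pupil_cohort()].
#' @param window_ms Reduction block width in ms (default 16).
#' @param max_missing_fraction Trial exclusion threshold (default 0.8).
#' @return A list: `cohort` (preprocessed [pupil_cohort()]) and `dropped`
#'   (data frame of subject_id, trial_id for excluded trials).
#' @export
preprocess_cohort <- function(cohort, window_ms = 16, max_missing_fraction = 0.8) {
  stopifnot(inherits(cohort, "pupil_cohort"))
  dropped <- list()
  subjects <- lapply(cohort$subjects, function(s) {
    ex <- exclude_trials(s$trials, max_missing_fraction)
    if (length(ex$dropped)) {
      dropped[[length(dropped) + 1L]] <<-
        data.frame(subject_id = s$subject_id, trial_id = ex$dropped,
                   stringsAsFactors = FALSE)
    }
    if (!length(ex$kept)) {
      stop(sprintf("all trials of subject '%s' were excluded", s$subject_id),
           call. = FALSE)
    }
    s$trials <- lapply(ex$kept, function(tr) {
      reduce_series(interpolate_missing(tr), window_ms = window_ms)
    })
    s
  })
  list(cohort = pupil_cohort(subjects),
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(subject_id = character(), trial_id = character()))
}
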