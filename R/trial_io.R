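# Group labels used in files and throughout the package. "ADHD" is the
# positive (unmedicated ADHD-diagnosed) class, "CTRL" the healthy controls.
GROUP_LEVELS <- c("ADHD", "CTRL")

#' Construct a single pupillometry trial
#'
#' A trial is one continuous pupil-diameter recording for one subject,
#' sampled on a uniform millisecond time grid. Missing samples (blinks,
#' tracker dropouts) are encoded as `NA` in `pupil`.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param trial_id Trial identifier (coerced to character).
#' @param t_ms Numeric vector of sample times in milliseconds, strictly
#'   increasing with constant spacing.
#' @param pupil Numeric vector of pupil diameters (arbitrary units), same
#'   length as `t_ms`; `NA` marks a missing sample.
#' @param sample_period_ms Sample spacing in ms. Inferred from `t_ms` when
#'   `NULL`.
#' @return An object of class `pupil_trial`.
#' @export
pupil_trial <- function(subject_id, trial_id, t_ms, pupil,
                        sample_period_ms = NULL) {
  t_ms <- as.numeric(t_ms)
  pupil <- as.numeric(pupil)
  if (length(t_ms) != length(pupil)) {
    stop("t_ms and pupil must have the same length", call. = FALSE)
  }
  if (length(t_ms) < 2) {
    stop("a trial needs at least 2 samples", call. = FALSE)
  }
  d <- diff(t_ms)
  if (any(d <= 0)) {
    stop(sprintf("t_ms must be strictly increasing (trial '%s', subject '%s')",
                 trial_id, subject_id), call. = FALSE)
  }
  if (max(d) - min(d) > 1e-6 * max(d)) {
    stop(sprintf("t_ms must be uniformly spaced (trial '%s', subject '%s')",
                 trial_id, subject_id), call. = FALSE)
  }
  period <- if (is.null(sample_period_ms)) d[1] else as.numeric(sample_period_ms)
  if (abs(period - d[1]) > 1e-6 * period) {
    stop("sample_period_ms does not match the spacing of t_ms", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         t_ms = t_ms, pupil = pupil,
         sample_period_ms = period),
    class = "pupil_trial")
}

#' @export
print.pupil_trial <- function(x, ...) {
  cat(sprintf("<pupil_trial> subject %s, trial %s: %d samples @ %g ms (%d missing)\n",
              x$subject_id, x$trial_id, length(x$pupil), x$sample_period_ms,
              sum(is.na(x$pupil))))
  invisible(x)
}

#' Construct a cohort of subjects
#'
#' @param subjects A list; each element is a list with fields `subject_id`,
#'   `group` (`"ADHD"` or `"CTRL"`) and `trials` (a non-empty list of
#'   [pupil_trial()] objects).
#' @return An object of class `pupil_cohort`.
#' @export
pupil_cohort <- function(subjects) {
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop("subject ids must be unique", call. = FALSE)
  }
  for (s in subjects) {
    if (!s$group %in% GROUP_LEVELS) {
      stop(sprintf("unknown group label '%s' for subject '%s'",
                   s$group, s$subject_id), call. = FALSE)
    }
    if (length(s$trials) < 1) {
      stop(sprintf("subject '%s' has no trials", s$subject_id), call. = FALSE)
    }
  }
  structure(list(subjects = subjects), class = "pupil_cohort")
}

#' @export
print.pupil_cohort <- function(x, ...) {
  g <- cohort_groups(x)
  cat(sprintf("<pupil_cohort> %d subjects (%d ADHD, %d CTRL), %d trials total\n",
              length(x$subjects), sum(g == "ADHD"), sum(g == "CTRL"),
              sum(vapply(x$subjects, function(s) length(s$trials), integer(1)))))
  invisible(x)
}

#' Subject ids of a cohort
#' @param cohort A [pupil_cohort()].
#' @return Character vector of subject ids.
#' @export
cohort_subject_ids <- function(cohort) {
  vapply(cohort$subjects, function(s) s$subject_id, character(1))
}

#' Group labels of a cohort
#' @param cohort A [pupil_cohort()].
#' @return Character vector of group labels ("ADHD"/"CTRL"), one per subject.
#' @export
cohort_groups <- function(cohort) {
  vapply(cohort$subjects, function(s) s$group, character(1))
}

#' Read a long-format trial table into a cohort
#'
#' Expects a CSV with one row per sample and columns `subject_id`, `group`,
#' `trial_id`, `t_ms`, `pupil` (names remappable through `dialect`). Blank
#' or `NA` pupil cells become missing samples. Rows may arrive in any order
#' across trials; within each trial they are sorted by `t_ms`, and a
#' non-monotonic or non-uniform time axis is a validation error.
#'
#' @param path Path to the CSV file.
#' @param dialect Named character vector mapping canonical column names to
#'   the names used in the file, e.g. `c(pupil = "diameter")`.
#' @return A [pupil_cohort()].
#' @export
read_trials <- function(path, dialect = character()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "NaN", ""))
  canonical <- c("subject_id", "group", "trial_id", "t_ms", "pupil")
  for (col in canonical) {
    actual <- if (col %in% names(dialect)) dialect[[col]] else col
    if (!actual %in% names(df)) {
      stop(sprintf("missing required column '%s' (looked for '%s')",
                   col, actual), call. = FALSE)
    }
    names(df)[names(df) == actual] <- col
  }
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }

  # subjects and trials are ordered by id so that row order in the file
  # never influences the resulting cohort
  subjects <- list()
  for (sid in sort(unique(df$subject_id))) {
    sdf <- df[df$subject_id == sid, , drop = FALSE]
    grp <- unique(sdf$group)
    if (length(grp) != 1) {
      stop(sprintf("subject '%s' has inconsistent group labels", sid),
           call. = FALSE)
    }
    trials <- lapply(sort(unique(sdf$trial_id)), function(tid) {
      tdf <- sdf[sdf$trial_id == tid, , drop = FALSE]
      if (anyDuplicated(tdf$t_ms)) {
        stop(sprintf("duplicate t_ms in trial '%s' of subject '%s'", tid, sid),
             call. = FALSE)
      }
      tdf <- tdf[order(tdf$t_ms), , drop = FALSE]
      pupil_trial(sid, tid, tdf$t_ms, tdf$pupil)
    })
    subjects[[length(subjects) + 1L]] <-
      list(subject_id = as.character(sid), group = grp, trials = trials)
  }
  pupil_cohort(subjects)
}

#' Write a cohort back to the long CSV layout
#'
#' Inverse of [read_trials()]; missing samples are written as empty cells.
#'
#' @param cohort A [pupil_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(cohort, path) {
  rows <- lapply(cohort$subjects, function(s) {
    do.call(rbind, lapply(s$trials, function(tr) {
      data.frame(subject_id = s$subject_id, group = s$group,
                 trial_id = tr$trial_id, t_ms = tr$t_ms, pupil = tr$pupil,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Construct a subjects-by-features matrix with group labels
#'
#' @param subject_ids Character vector of subject ids (unique).
#' @param groups Character vector of group labels, one per subject.
#' @param values Numeric matrix or data frame, one row per subject, one
#'   column per feature; all values finite.
#' @param feature_names Optional character vector of feature names; defaults
#'   to the column names of `values`.
#' @return A `feature_matrix`: a data frame with columns `subject_id`,
#'   `group`, then one numeric column per feature.
#' @export
feature_matrix <- function(subject_ids, groups, values, feature_names = NULL) {
  values <- as.matrix(values)
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names) || !length(feature_names)) {
    stop("feature_matrix needs at least one named feature", call. = FALSE)
  }
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique", call. = FALSE)
  }
  if (nrow(values) != length(subject_ids) || length(groups) != length(subject_ids)) {
    stop("subject_ids, groups and rows of values must align", call. = FALSE)
  }
  if (ncol(values) != length(feature_names)) {
    stop("values must have one column per feature name", call. = FALSE)
  }
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique", call. = FALSE)
  if (!all(groups %in% GROUP_LEVELS)) {
    stop("group labels must be 'ADHD' or 'CTRL'", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("feature values must all be finite", call. = FALSE)
  }
  df <- data.frame(subject_id = as.character(subject_ids),
                   group = as.character(groups),
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(values)
  names(vals) <- feature_names
  out <- cbind(df, vals)
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Feature names of a feature matrix
#' @param fm A `feature_matrix`.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(fm) {
  setdiff(names(fm), c("subject_id", "group"))
}

#' Numeric feature values of a feature matrix
#' @param fm A `feature_matrix`.
#' @return Numeric matrix (subjects x features) with subject ids as rownames.
#' @export
feature_values <- function(fm) {
  m <- as.matrix(fm[, feature_names(fm), drop = FALSE])
  rownames(m) <- fm$subject_id
  m
}

#' Write a feature matrix to CSV
#'
#' Header is `subject_id,group,<feature names...>`. Values are written with
#' enough digits (15 significant) for a bit-faithful round trip at double
#' precision for typical magnitudes.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!length(feature_names(fm))) {
    stop("refusing to write a feature matrix with no features", call. = FALSE)
  }
  out <- fm
  class(out) <- "data.frame"
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  for (i in seq_len(nrow(out))) {
    vals <- vapply(feature_names(fm),
                   function(f) format(out[[f]][i], digits = 17, scientific = TRUE),
                   character(1))
    writeLines(paste(c(out$subject_id[i], out$group[i], vals), collapse = ","), con)
  }
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path CSV path.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "group")
  for (col in need) {
    if (!col %in% names(df)) {
      stop(sprintf("missing required column '%s'", col), call. = FALSE)
    }
  }
  feats <- setdiff(names(df), need)
  feature_matrix(df$subject_id, df$group,
                 as.matrix(df[, feats, drop = FALSE]), feats)
}

# ms -> 0-based sample index, half-open window convention [start, end)
ms_to_index <- function(ms, sample_period_ms) {
  as.integer(floor(ms / sample_period_ms))
}

# 0-based half-open [start_ms, end_ms) window as 1-based R index range
window_indices <- function(trial, start_ms, end_ms) {
  n <- length(trial$pupil)
  i0 <- ms_to_index(start_ms, trial$sample_period_ms)
  i1 <- ms_to_index(end_ms, trial$sample_period_ms)
  i0 <- max(i0, 0L)
  i1 <- min(i1, n)
  if (i0 >= i1) {
    stop(sprintf("window [%g, %g) ms is empty for a %d-sample trial at %g ms",
                 start_ms, end_ms, n, trial$sample_period_ms), call. = FALSE)
  }
  seq.int(i0 + 1L, i1)
}
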