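#' RadViz projection of a feature matrix
#'
#' Features are placed as anchors uniformly on the unit circle
#' (`theta_j = 2*pi*j/m`, in `feature_subset` order); each subject is
#' placed at the normalized-value-weighted mean of the anchor positions:
#' `point_i = sum_j x_ij * u_j / sum_j x_ij` after min-max normalizing each
#' feature column to \[0, 1\]. Every point therefore lies in the convex
#' hull of the anchors (inside the unit circle); a subject whose
#' normalized values are all zero sits at the origin by convention.
#'
#' @param fm A `feature_matrix`.
#' @param feature_subset Character vector (>= 2) of feature names; anchor
#'   order follows this order.
#' @return A `radviz_projection`: list with `anchors` (feature, theta, x,
#'   y), `points` (subject_id, group, x, y) and `normalization` (feature,
#'   min, max).
#' @export
radviz_project <- function(fm, feature_subset) {
  stopifnot(inherits(fm, "feature_matrix"))
  feature_subset <- as.character(feature_subset)
  if (length(feature_subset) < 2) {
    stop("RadViz needs at least 2 features", call. = FALSE)
  }
  missing_f <- setdiff(feature_subset, feature_names(fm))
  if (length(missing_f)) {
    stop(sprintf("unknown feature(s): %s", paste(missing_f, collapse = ", ")),
         call. = FALSE)
  }
  V <- feature_values(fm)[, feature_subset, drop = FALSE]
  mins <- apply(V, 2, min)
  maxs <- apply(V, 2, max)
  const <- maxs == mins
  if (any(const)) {
    stop(sprintf("constant feature(s) cannot be min-max normalized: %s",
                 paste(feature_subset[const], collapse = ", ")), call. = FALSE)
  }
  Z <- sweep(sweep(V, 2, mins), 2, maxs - mins, "/")

  m <- length(feature_subset)
  theta <- 2 * pi * (seq_len(m) - 1) / m
  ux <- cos(theta); uy <- sin(theta)
  wsum <- rowSums(Z)
  px <- ifelse(wsum == 0, 0, (Z %*% ux) / wsum)
  py <- ifelse(wsum == 0, 0, (Z %*% uy) / wsum)

  structure(list(
    anchors = data.frame(feature = feature_subset, theta = theta,
                         x = ux, y = uy, stringsAsFactors = FALSE),
    points = data.frame(subject_id = fm$subject_id, group = fm$group,
                        x = as.numeric(px), y = as.numeric(py),
                        stringsAsFactors = FALSE),
    normalization = data.frame(feature = feature_subset, min = mins,
                               max = maxs, row.names = NULL,
                               stringsAsFactors = FALSE)),
    class = "radviz_projection")
}

save_figure <- function(plot, path, width = 7, height = 5) {
  ggplot2::ggsave(path, plot, width = width, height = height, dpi = 120)
  invisible(path)
}

#' Plot a RadViz projection to a file
#'
#' @param projection A `radviz_projection` from [radviz_project()].
#' @param path Output image path (extension picks the device, e.g. `.png`).
#' @return `path`, invisibly.
#' @export
plot_radviz <- function(projection, path) {
  circ <- data.frame(theta = seq(0, 2 * pi, length.out = 200))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = cos(.data$theta), y = sin(.data$theta)),
                       color = "grey60") +
    ggplot2::geom_point(data = projection$points,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$group), size = 2) +
    ggplot2::geom_text(data = projection$anchors,
                       ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                                    label = .data$feature), size = 2.6) +
    ggplot2::coord_equal(xlim = c(-1.35, 1.35), ylim = c(-1.35, 1.35)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, color = "Group")
  save_figure(p, path, width = 6.5, height = 6)
}

#' Group-mean line plot of pupil size, dilation velocity or acceleration
#'
#' Velocity and acceleration are computed from the group-mean series (not
#' averaged per-trial derivatives), anchored at the probe sample, and
#' plotted from the probe onward; `"size"` plots the whole trial with the
#' probe marked.
#'
#' @param cohort A preprocessed (fully observed) [pupil_cohort()].
#' @param derivative One of `"size"`, `"velocity"`, `"acceleration"`.
#' @param path Output image path.
#' @param timing A [probe_timing()].
#' @return `path`, invisibly.
#' @export
group_mean_lineplot <- function(cohort, derivative = c("size", "velocity",
                                                       "acceleration"),
                                path, timing = probe_timing()) {
  derivative <- match.arg(derivative)
  df <- group_mean_series(cohort, derivative, timing)
  ylab <- switch(derivative,
                 size = "Mean pupil size (a.u.)",
                 velocity = "Dilation velocity (a.u./ms)",
                 acceleration = "Dilation acceleration (a.u./ms²)")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$value,
                                        color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = timing$probe_ms, linetype = "dashed",
                        color = "grey40") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "Time (ms)", y = ylab, color = "Group")
  save_figure(p, path)
}

# shared computation behind the line plots, exposed for testing
group_mean_series <- function(cohort, derivative, timing = probe_timing()) {
  sm <- summarize_cohort(cohort)
  if (derivative == "size") {
    names(sm)[names(sm) == "mean_pupil"] <- "value"
    return(sm)
  }
  out <- list()
  for (g in unique(sm$group)) {
    gd <- sm[sm$group == g, ]
    tr <- pupil_trial("groupmean", g, gd$t_ms, gd$mean_pupil)
    probe_i <- ms_to_index(timing$probe_ms, tr$sample_period_ms)
    v <- if (derivative == "velocity") dilation_velocity(tr, probe_i) else
      dilation_acceleration(tr, probe_i)
    out[[g]] <- data.frame(group = g,
                           t_ms = gd$t_ms[seq.int(probe_i + 1L, nrow(gd))],
                           value = v, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Box or violin plot of one feature by group, annotated with its p-value
#'
#' The annotation carries the two-sided Mann-Whitney p-value for the
#' ADHD-vs-control comparison of the plotted feature.
#'
#' @param fm A `feature_matrix`.
#' @param feature Feature name to plot.
#' @param style `"box"` or `"violin"`.
#' @param path Output image path.
#' @return `path`, invisibly.
#' @export
feature_distribution_plot <- function(fm, feature, style = c("box", "violin"),
                                      path) {
  style <- match.arg(style)
  if (!feature %in% feature_names(fm)) {
    stop(sprintf("unknown feature '%s'", feature), call. = FALSE)
  }
  v <- fm[[feature]]
  pos <- fm$group == "ADHD"
  mw <- mann_whitney_u(v[pos], v[!pos])
  df <- data.frame(group = fm$group, value = v)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                        fill = .data$group))
  p <- p + if (style == "box") ggplot2::geom_boxplot() else
    ggplot2::geom_violin()
  p <- p +
    ggplot2::annotate("text", x = 1.5, y = max(v),
                      label = sprintf("p = %.3g", mw$p), vjust = -0.4) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = feature, fill = "Group")
  save_figure(p, path)
}

#' Pooled ROC curves per classifier, one panel
#'
#' @param roc_points Data frame with columns `repetition`, `fpr`, `tpr`
#'   (e.g. `report$roc_points`), optionally a `classifier` column for
#'   multiple models.
#' @param path Output image path.
#' @return `path`, invisibly.
#' @export
plot_roc_curves <- function(roc_points, path) {
  if (!"classifier" %in% names(roc_points)) roc_points$classifier <- "model"
  p <- ggplot2::ggplot(roc_points,
                       ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    group = interaction(.data$classifier,
                                                        .data$repetition),
                                    color = .data$classifier)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  color = NULL)
  save_figure(p, path, width = 6, height = 6)
}
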