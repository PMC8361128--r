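#' Default pipeline configuration
#'
#' Every protocol constant is a config default rather than a hard-coded
#' value: the 16 ms reduction window, the 0.8 missing-fraction exclusion
#' threshold, the 5000 ms probe, 9 features selected per fold, 10 outer and
#' 5 inner folds, 40 repetitions. The `simulate` section holds the
#' synthetic-cohort settings used when no input CSV is given.
#'
#' @return A nested list of configuration sections
#'   (`io`, `preprocess`, `features`, `stats`, `evaluation`, `simulate`,
#'   `plot`).
#' @export
default_pipeline_config <- function() {
  list(
    io = list(input_csv = NULL, out_dir = "results"),
    preprocess = list(window_ms = 16, max_missing_fraction = 0.8),
    features = list(probe_ms = 5000, trial_end_ms = 8000,
                    item19 = "literal",
                    general = list(fft_k = 2, ql = 0.4, qh = 0.8,
                                   apen_m = 2, apen_r_factor = 0.2,
                                   peaks_n = 10)),
    stats = list(method = "mann_whitney", adjust = FALSE),
    evaluation = list(classifiers = c("svm", "logistic_regression"),
                      outer_folds = 10, inner_folds = 5, k_select = 9,
                      repetitions = 40, ci_mode = "se", seed = 1),
    simulate = list(enabled = TRUE, n_adhd = 28, n_ctrl = 22,
                    trials_per_subject = 160, duration_ms = 8000,
                    sampling_hz = 1000, effect = "strong", seed = 1),
    plot = list(enabled = TRUE, radviz_top = 9)
  )
}

# recursive defaults merge: user values win, unknown keys are an error
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown config key '%s'", here), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys raise a schema error naming the key path; omitted keys take
#' the defaults of [default_pipeline_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  ev <- cfg$evaluation
  n_features <- length(list_custom_features()) +
    length(list_general_features())
  if (ev$k_select > n_features) {
    stop(sprintf(
      "evaluation.k_select = %d exceeds the %d features of the default registry",
      ev$k_select, n_features), call. = FALSE)
  }
  if (ev$k_select < 1) stop("evaluation.k_select must be >= 1", call. = FALSE)
  if (!all(ev$classifiers %in% CLASSIFIER_NAMES)) {
    stop(sprintf("evaluation.classifiers: unknown name(s) %s",
                 paste(setdiff(ev$classifiers, CLASSIFIER_NAMES),
                       collapse = ", ")), call. = FALSE)
  }
  if (!(cfg$preprocess$max_missing_fraction > 0 &&
        cfg$preprocess$max_missing_fraction <= 1)) {
    stop("preprocess.max_missing_fraction must be in (0, 1]", call. = FALSE)
  }
  if (is.null(cfg$io$input_csv) && !isTRUE(cfg$simulate$enabled)) {
    stop("either io.input_csv or simulate.enabled is required", call. = FALSE)
  }
  invisible(cfg)
}

#' Run the full screening pipeline
#'
#' Simulate (or read) trials, preprocess, build the feature matrix, rank
#' features, evaluate the configured classifiers with repeated nested CV,
#' and write all artifacts plus a run manifest into the output directory.
#' Identical config and seed give identical outputs.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   a path to a YAML file.
#' @param out_dir Output directory; overrides `config$io$out_dir` when
#'   given.
#' @return The output directory path, invisibly; artifacts:
#'   `trials.csv` (when simulated), `feature_matrix.csv`,
#'   `ranked_features.csv`, `evaluation_<classifier>.json`, `roc.csv`,
#'   `figures/`, `manifest.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  out_dir <- if (is.null(out_dir)) config$io$out_dir else out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  timing <- probe_timing(config$features$probe_ms, config$features$trial_end_ms)

  if (!is.null(config$io$input_csv)) {
    cohort <- read_trials(config$io$input_csv)
    truth <- NULL
  } else {
    sim <- config$simulate
    gen <- generate_cohort(generator_config(
      n_adhd = sim$n_adhd, n_ctrl = sim$n_ctrl,
      trials_per_subject = sim$trials_per_subject,
      duration_ms = sim$duration_ms, sampling_hz = sim$sampling_hz,
      probe_ms = config$features$probe_ms,
      effect = sim$effect, seed = sim$seed))
    cohort <- gen$cohort
    truth <- gen$truth
    write_trials(cohort, file.path(out_dir, "trials.csv"))
  }

  message("preprocessing trials")
  pp <- preprocess_cohort(cohort,
                          window_ms = config$preprocess$window_ms,
                          max_missing_fraction = config$preprocess$max_missing_fraction)
  message(sprintf("  %d trials excluded for missingness", nrow(pp$dropped)))

  message("building feature matrix")
  g <- config$features$general
  specs <- default_feature_specs(timing = timing,
                                 item19 = config$features$item19,
                                 fft_k = g$fft_k, ql = g$ql, qh = g$qh,
                                 apen_m = g$apen_m,
                                 apen_r_factor = g$apen_r_factor,
                                 peaks_n = g$peaks_n)
  fm <- build_feature_matrix(pp$cohort, specs, timing = timing,
                             item19 = config$features$item19)
  write_feature_matrix(fm, file.path(out_dir, "feature_matrix.csv"))

  message("ranking features")
  ranked <- rank_features(fm, method = config$stats$method,
                          adjust = config$stats$adjust)
  write_ranked_features(ranked, file.path(out_dir, "ranked_features.csv"))

  roc_all <- list()
  for (clf in config$evaluation$classifiers) {
    message(sprintf("nested CV: %s", clf))
    rep <- nested_cv(fm, classifier_spec(clf,
                                         inner_folds = config$evaluation$inner_folds),
                     outer_folds = config$evaluation$outer_folds,
                     k_select = config$evaluation$k_select,
                     repetitions = config$evaluation$repetitions,
                     seed = config$evaluation$seed,
                     ci = config$evaluation$ci_mode)
    write_evaluation_report(rep, file.path(out_dir,
                                           sprintf("evaluation_%s.json", clf)))
    roc_all[[clf]] <- cbind(classifier = clf, rep$roc_points)
  }
  roc_df <- do.call(rbind, roc_all)
  utils::write.csv(roc_df, file.path(out_dir, "roc.csv"), row.names = FALSE)

  if (isTRUE(config$plot$enabled)) {
    fig_dir <- file.path(out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    group_mean_lineplot(pp$cohort, "size",
                        file.path(fig_dir, "group_mean_size.png"), timing)
    group_mean_lineplot(pp$cohort, "velocity",
                        file.path(fig_dir, "group_mean_velocity.png"), timing)
    top <- select_top_k(ranked, min(config$plot$radviz_top,
                                    nrow(ranked)))
    proj <- radviz_project(fm, top)
    plot_radviz(proj, file.path(fig_dir, "radviz_top_features.png"))
    feature_distribution_plot(fm, "size_std", "box",
                              file.path(fig_dir, "size_std_box.png"))
    plot_roc_curves(roc_df, file.path(fig_dir, "roc.png"))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("pupilscreen")),
                   seed = config$evaluation$seed,
                   config = config,
                   n_subjects = length(cohort$subjects),
                   n_trials_dropped = nrow(pp$dropped),
                   n_features = length(feature_names(fm)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
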