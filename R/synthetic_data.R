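#' Configuration for the synthetic pupillometry cohort generator
#'
#' Defaults emulate the screening study's cohort: 28 unmedicated-ADHD and
#' 22 control children, 160 trials per subject, 8 s trials sampled at
#' 1 kHz, probe at 5000 ms. Group parameters encode the qualitative
#' contrasts the analysis is built to detect: controls show a larger and
#' faster stimulus-evoked dilation (bigger amplitude, shorter rise time
#' constant) and larger slow variability; the ADHD group carries more
#' sample-to-sample high-frequency jitter (higher approximate entropy,
#' more peaks, larger consecutive-change variance). `effect = "null"`
#' gives both groups the control parameters, `"moderate"` halves every
#' group gap.
#'
#' All amplitudes are in arbitrary pupil units; time constants in ms.
#' Noise is an AR(1) process parameterized by its stationary sd and
#' correlation time (so realizations are comparable across sampling
#' rates), plus white jitter. Blinks are Poisson-arriving missing runs
#' with lognormal durations; a small fraction of trials are
#' "catastrophic", losing a contiguous ~85-95% of samples so the
#' exclusion rule has real work.
#'
#' @param n_adhd,n_ctrl Subjects per group (defaults 28, 22).
#' @param trials_per_subject Trials per subject (default 160).
#' @param duration_ms Trial length in ms (default 8000).
#' @param sampling_hz Sampling rate (default 1000).
#' @param probe_ms Probe time in ms (default 5000).
#' @param effect `"strong"`, `"moderate"` or `"null"`.
#' @param baseline_mean,baseline_sd Between-subject baseline pupil size.
#' @param amp_ctrl,amp_adhd Mean evoked amplitude per group.
#' @param amp_sd Between-subject amplitude sd.
#' @param tau_ctrl,tau_adhd Mean dilation rise time constant per group (ms).
#' @param tau_sd Between-subject time-constant sd (ms).
#' @param ar_sd_ctrl,ar_sd_adhd Stationary sd of the slow AR(1) noise.
#' @param ar_sd_sd Between-subject sd of the AR(1) stationary sd.
#' @param ar_tau_ms AR(1) correlation time (ms).
#' @param jitter_ctrl,jitter_adhd White high-frequency jitter sd per group.
#' @param jitter_sd Between-subject jitter sd.
#' @param decay_tau_ms Post-plateau decay time constant after
#'   `probe_ms + 2000` ms.
#' @param blink_rate_hz Blink arrivals per second (default 0.25).
#' @param blink_meanlog,blink_sdlog Lognormal blink duration (ms) params.
#' @param catastrophic_prob Per-trial probability of a catastrophic
#'   missing run (default 0.02).
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_adhd = 28L, n_ctrl = 22L,
                             trials_per_subject = 160L,
                             duration_ms = 8000, sampling_hz = 1000,
                             probe_ms = 5000,
                             effect = c("strong", "moderate", "null"),
                             baseline_mean = 3.0, baseline_sd = 0.25,
                             amp_ctrl = 0.85, amp_adhd = 0.60, amp_sd = 0.15,
                             tau_ctrl = 280, tau_adhd = 430, tau_sd = 45,
                             ar_sd_ctrl = 0.30, ar_sd_adhd = 0.20,
                             ar_sd_sd = 0.05, ar_tau_ms = 200,
                             jitter_ctrl = 0.015, jitter_adhd = 0.050,
                             jitter_sd = 0.010,
                             decay_tau_ms = 600,
                             blink_rate_hz = 0.25,
                             blink_meanlog = log(120), blink_sdlog = 0.35,
                             catastrophic_prob = 0.02,
                             seed = 1L) {
  effect <- match.arg(effect)
  stopifnot(n_adhd >= 1, n_ctrl >= 1, trials_per_subject >= 1,
            probe_ms < duration_ms, sampling_hz > 0)
  cfg <- as.list(environment())
  # shrink or remove the group gaps
  if (effect != "strong") {
    w <- if (effect == "moderate") 0.5 else 0
    cfg$amp_adhd <- cfg$amp_ctrl + w * (amp_adhd - amp_ctrl)
    cfg$tau_adhd <- cfg$tau_ctrl + w * (tau_adhd - tau_ctrl)
    cfg$ar_sd_adhd <- cfg$ar_sd_ctrl + w * (ar_sd_adhd - ar_sd_ctrl)
    cfg$jitter_adhd <- cfg$jitter_ctrl + w * (jitter_adhd - jitter_ctrl)
  }
  structure(cfg, class = "generator_config")
}

# one trial's noiseless evoked response on time grid t (ms)
evoked_response <- function(t, probe_ms, amp, tau, decay_tau_ms) {
  plateau_ms <- probe_ms + 2000
  y <- numeric(length(t))
  up <- t >= probe_ms & t < plateau_ms
  y[up] <- amp * (1 - exp(-(t[up] - probe_ms) / tau))
  down <- t >= plateau_ms
  if (any(down)) {
    y_at <- amp * (1 - exp(-(plateau_ms - probe_ms) / tau))
    y[down] <- y_at * exp(-(t[down] - plateau_ms) / decay_tau_ms)
  }
  y
}

ar1_noise <- function(n, dt_ms, sd_stat, tau_ms) {
  rho <- exp(-dt_ms / tau_ms)
  innov_sd <- sd_stat * sqrt(1 - rho^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), rho,
                           method = "recursive",
                           init = stats::rnorm(1, 0, sd_stat)))
}

insert_blinks <- function(pupil, dt_ms, rate_hz, meanlog, sdlog) {
  n <- length(pupil)
  total_ms <- n * dt_ms
  n_blinks <- stats::rpois(1, rate_hz * total_ms / 1000)
  if (n_blinks > 0) {
    starts <- stats::runif(n_blinks, 0, total_ms)
    durs <- stats::rlnorm(n_blinks, meanlog, sdlog)
    for (b in seq_len(n_blinks)) {
      i0 <- max(1L, 1L + floor(starts[b] / dt_ms))
      i1 <- min(n, ceiling((starts[b] + durs[b]) / dt_ms))
      if (i0 <= i1) pupil[i0:i1] <- NA_real_
    }
  }
  pupil
}

#' Generate a synthetic task-evoked pupillometry cohort
#'
#' Each trial is `baseline + evoked(t) + AR(1) slow noise + white jitter`,
#' where the evoked term is a saturating exponential rising from the probe
#' (amplitude and rise time constant are the group-discriminating
#' parameters) that plateaus and then decays after `probe_ms + 2000` ms.
#' Subject-level parameters are drawn once per subject around the group
#' means; trials add amplitude jitter and baseline drift. Blink-like
#' missing runs and occasional catastrophic trials are inserted. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list: `cohort` (a [pupil_cohort()], raw, with missing samples)
#'   and `truth` (data frame of per-subject realized parameters).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(config$seed) %% .Machine$integer.max)
  dt <- 1000 / config$sampling_hz
  n_samp <- floor(config$duration_ms / dt)
  t_ms <- (seq_len(n_samp) - 1) * dt

  groups <- c(rep("ADHD", config$n_adhd), rep("CTRL", config$n_ctrl))
  ids <- sprintf("S%03d", seq_along(groups))

  truth <- data.frame(subject_id = ids, group = groups,
                      baseline = NA_real_, amp = NA_real_, tau = NA_real_,
                      ar_sd = NA_real_, jitter_sd = NA_real_,
                      stringsAsFactors = FALSE)
  subjects <- vector("list", length(ids))
  for (si in seq_along(ids)) {
    g <- groups[si]
    amp_mu <- if (g == "ADHD") config$amp_adhd else config$amp_ctrl
    tau_mu <- if (g == "ADHD") config$tau_adhd else config$tau_ctrl
    ar_mu <- if (g == "ADHD") config$ar_sd_adhd else config$ar_sd_ctrl
    jit_mu <- if (g == "ADHD") config$jitter_adhd else config$jitter_ctrl

    baseline <- stats::rnorm(1, config$baseline_mean, config$baseline_sd)
    amp <- max(0.05, stats::rnorm(1, amp_mu, config$amp_sd))
    tau <- max(50, stats::rnorm(1, tau_mu, config$tau_sd))
    ar_sd <- max(0.02, stats::rnorm(1, ar_mu, config$ar_sd_sd))
    jit <- max(0.001, stats::rnorm(1, jit_mu, config$jitter_sd))
    truth[si, c("baseline", "amp", "tau", "ar_sd", "jitter_sd")] <-
      c(baseline, amp, tau, ar_sd, jit)

    trials <- vector("list", config$trials_per_subject)
    for (ti in seq_len(config$trials_per_subject)) {
      amp_t <- amp * stats::rnorm(1, 1, 0.15)
      base_t <- baseline + stats::rnorm(1, 0, 0.05)
      p <- base_t +
        evoked_response(t_ms, config$probe_ms, amp_t, tau, config$decay_tau_ms) +
        ar1_noise(n_samp, dt, ar_sd, config$ar_tau_ms) +
        stats::rnorm(n_samp, 0, jit)
      if (stats::runif(1) < config$catastrophic_prob) {
        frac <- stats::runif(1, 0.85, 0.95)
        len <- floor(frac * n_samp)
        start <- sample.int(n_samp - len, 1)
        p[start:(start + len - 1L)] <- NA_real_
      } else {
        p <- insert_blinks(p, dt, config$blink_rate_hz,
                           config$blink_meanlog, config$blink_sdlog)
        # the imputation contract needs observed endpoints somewhere:
        # guarantee at least 4 observed samples survive
        if (sum(!is.na(p)) < 4) p[1:4] <- base_t
      }
      trials[[ti]] <- pupil_trial(ids[si], sprintf("T%03d", ti), t_ms, p,
                                  sample_period_ms = dt)
    }
    subjects[[si]] <- list(subject_id = ids[si], group = g, trials = trials)
  }
  list(cohort = pupil_cohort(subjects), truth = truth)
}

#' Per-group mean pupil time course
#'
#' Pointwise mean over all trials of all subjects in each group (trials
#' must share a common time grid, i.e. the cohort is preprocessed or
#' generated without missing samples). The study's qualitative signature
#' is a larger post-probe peak for controls.
#'
#' @param cohort A fully observed [pupil_cohort()].
#' @return Data frame with columns `group`, `t_ms`, `mean_pupil`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "pupil_cohort"))
  out <- list()
  for (g in unique(cohort_groups(cohort))) {
    subj <- cohort$subjects[cohort_groups(cohort) == g]
    trials <- unlist(lapply(subj, `[[`, "trials"), recursive = FALSE)
    if (anyNA(unlist(lapply(trials, `[[`, "pupil")))) {
      stop("summarize_cohort requires fully observed trials; preprocess first",
           call. = FALSE)
    }
    n_min <- min(vapply(trials, function(tr) length(tr$pupil), integer(1)))
    m <- rowMeans(vapply(trials, function(tr) tr$pupil[seq_len(n_min)],
                         numeric(n_min)))
    out[[g]] <- data.frame(group = g,
                           t_ms = trials[[1]]$t_ms[seq_len(n_min)],
                           mean_pupil = m, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
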