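# Independent oracles, written directly from the defining formulas and kept
# deliberately naive (loops, O(N^2)) so they share no code path with the
# package implementations they check.

# trial on a 0-based uniform ms grid
make_trial <- function(pupil, period_ms = 1, subject = "s1", trial = "t1") {
  pupil_trial(subject, trial, (seq_along(pupil) - 1) * period_ms, pupil,
              sample_period_ms = period_ms)
}

oracle_energy <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  s
}

oracle_dft_real <- function(x, k) {
  n <- length(x)
  s <- 0
  for (j in seq_len(n)) {
    s <- s + x[j] * cos(-2 * pi * k * (j - 1) / n)
  }
  s
}

# corridor feature, literal: collect |diff| where both endpoints lie inside
# [q(ql), q(qh)], return the population variance of the collected values
oracle_change_quantiles <- function(x, ql, qh) {
  lo <- as.numeric(quantile(x, ql))
  hi <- as.numeric(quantile(x, qh))
  d <- c()
  for (i in seq_len(length(x) - 1)) {
    if (x[i] >= lo && x[i] <= hi && x[i + 1] >= lo && x[i + 1] <= hi) {
      d <- c(d, abs(x[i + 1] - x[i]))
    }
  }
  if (length(d) < 2) return(0)
  mean((d - mean(d))^2)
}

# literal Pincus ApEn: double loop over template pairs, Chebyshev distance,
# self-match included
oracle_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    logc <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        dmax <- 0
        for (k in 0:(mm - 1)) {
          dmax <- max(dmax, abs(x[i + k] - x[j + k]))
        }
        if (dmax <= r) cnt <- cnt + 1
      }
      logc[i] <- log(cnt / nt)
    }
    mean(logc)
  }
  phi(m) - phi(m + 1)
}

oracle_peaks <- function(x, n) {
  count <- 0
  for (i in seq_len(length(x))) {
    if (i <= n || i > length(x) - n) next
    ok <- TRUE
    for (lag in 1:n) {
      if (x[i] <= x[i - lag] || x[i] <= x[i + lag]) { ok <- FALSE; break }
    }
    if (ok) count <- count + 1
  }
  count
}

# trapezoidal AUROC by explicit threshold sweep over all distinct scores
oracle_auroc_trapezoid <- function(y_true, score) {
  ths <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0); fpr <- c(0)
  for (th in ths) {
    tpr <- c(tpr, sum(score >= th & y_true) / sum(y_true))
    fpr <- c(fpr, sum(score >= th & !y_true) / sum(!y_true))
  }
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# small synthetic feature matrix built directly from random numbers:
# `informative` columns get a group mean shift of `delta` sds
make_random_fm <- function(n_pos = 10, n_neg = 10, n_features = 12,
                           informative = 0, delta = 2, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  groups <- c(rep("ADHD", n_pos), rep("CTRL", n_neg))
  V <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(NULL, sprintf("f%02d", seq_len(n_features))))
  if (informative > 0) {
    V[groups == "ADHD", seq_len(informative)] <-
      V[groups == "ADHD", seq_len(informative)] + delta
  }
  feature_matrix(sprintf("s%02d", seq_len(n)), groups, V)
}
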