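#' Mann-Whitney U test (two-sided)
#'
#' The statistic is `U_x = sum(ranks of x) - n_x (n_x + 1) / 2` with
#' midranks for ties, so `U_x + U_y = n_x * n_y` always. For small untied
#' samples (`n_x + n_y <= exact_max`, no ties) the two-sided p-value comes
#' from exact enumeration of all label assignments
#' (`p = min(1, 2 * min(P(U <= u), P(U >= u)))`); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact_max Maximum pooled size for the exact path (default 12).
#' @return List with `U` (the statistic for `x`), `p` (two-sided p-value in
#'   \[0, 1\]) and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples contain missing values", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0

  if (!ties && n <= exact_max) {
    combos <- utils::combn(n, nx)
    rs <- rank(pooled)   # untied: a permutation of 1..n
    us <- colSums(matrix(rs[combos], nrow = nx)) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(us <= U), mean(us >= U)))
    return(list(U = U, p = p, method = "exact"))
  }

  mu <- nx * ny / 2
  tab <- table(pooled)
  tie_term <- sum(tab^3 - tab) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' One-way ANOVA F-test for a two-group feature
#'
#' `F = MSB / MSW` with degrees of freedom `(1, n - 2)`. For two groups this
#' equals the squared pooled-variance t statistic, and ranking features by F
#' is the standard univariate (squared point-biserial correlation) filter.
#' Zero pooled within-group variance with unequal means yields `F = Inf`,
#' `p = 0`; a fully constant feature yields `F = 0`, `p = 1`.
#'
#' @param values Numeric vector of per-subject feature values.
#' @param labels Vector with exactly two distinct values, aligned with
#'   `values`.
#' @return List with `F` and `p`.
#' @export
anova_f <- function(values, labels) {
  if (anyNA(values)) stop("values contain missing entries", call. = FALSE)
  g <- unique(labels)
  if (length(g) != 2) stop("labels must contain exactly two groups", call. = FALSE)
  a <- values[labels == g[1]]
  b <- values[labels == g[2]]
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 members", call. = FALSE)
  }
  n <- length(values)
  gm <- mean(values)
  ssb <- length(a) * (mean(a) - gm)^2 + length(b) * (mean(b) - gm)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  f <- ssb / (ssw / (n - 2))
  list(F = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

# vectorized two-group F over the columns of a matrix (selection hot path)
anova_f_columns <- function(values, positive) {
  n1 <- sum(positive); n2 <- sum(!positive); n <- n1 + n2
  m1 <- colMeans(values[positive, , drop = FALSE])
  m2 <- colMeans(values[!positive, , drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums((values[positive, , drop = FALSE] -
                    matrix(m1, n1, ncol(values), byrow = TRUE))^2) +
    colSums((values[!positive, , drop = FALSE] -
               matrix(m2, n2, ncol(values), byrow = TRUE))^2)
  f <- ifelse(ssw == 0, ifelse(ssb == 0, 0, Inf), ssb / (ssw / (n - 2)))
  p <- ifelse(is.infinite(f), 0,
              ifelse(f == 0 & ssw == 0, 1,
                     stats::pf(f, 1, n - 2, lower.tail = FALSE)))
  list(F = f, p = p)
}

#' Rank features by a univariate two-group statistic
#'
#' Computes the chosen statistic per feature column and sorts by p-value
#' ascending, ties broken by feature name for determinism. A constant
#' feature gets `p = 1` by convention. Benjamini-Hochberg adjusted p-values
#' can be appended but raw p-values drive the ranking.
#'
#' @param fm A `feature_matrix` with both groups present.
#' @param method `"mann_whitney"` (descriptive ranking) or `"anova_f"`
#'   (the selection filter used inside cross-validation folds).
#' @param adjust Add a `p_adjusted` (BH) column (default FALSE).
#' @return A `ranked_features` data frame: `feature`, `statistic`,
#'   `p_value` (and `p_adjusted` when requested), sorted; the method is
#'   stored in attribute `"method"`.
#' @export
rank_features <- function(fm, method = c("mann_whitney", "anova_f"),
                          adjust = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  method <- match.arg(method)
  groups <- fm$group
  if (length(unique(groups)) != 2) {
    stop("both groups must be present", call. = FALSE)
  }
  vals <- feature_values(fm)
  pos <- groups == "ADHD"
  res <- lapply(colnames(vals), function(f) {
    v <- vals[, f]
    if (max(v) == min(v)) {
      return(data.frame(feature = f, statistic = NA_real_, p_value = 1))
    }
    if (method == "mann_whitney") {
      mw <- mann_whitney_u(v[pos], v[!pos])
      data.frame(feature = f, statistic = mw$U, p_value = mw$p)
    } else {
      af <- anova_f(v, groups)
      data.frame(feature = f, statistic = af$F, p_value = af$p)
    }
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "method") <- method
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Take the top-k feature names from a ranking
#'
#' @param ranked A `ranked_features` data frame from [rank_features()].
#' @param k Number of features, default 9; must satisfy
#'   `1 <= k <= nrow(ranked)`.
#' @return Character vector of `k` feature names in rank order.
#' @export
select_top_k <- function(ranked, k = 9L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k > nrow(ranked)) {
    stop(sprintf("k = %d exceeds the %d available features", k, nrow(ranked)),
         call. = FALSE)
  }
  ranked$feature[seq_len(k)]
}

#' Write a feature ranking to CSV
#' @param ranked A `ranked_features` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_features <- function(ranked, path) {
  utils::write.csv(as.data.frame(ranked), path, row.names = FALSE)
  invisible(path)
}
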