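# Two-sample comparison of tree-statistic distributions.
#
# Three tests are offered: the classical two-sample Kolmogorov-Smirnov test
# (through stats::ks.test), and two location-scale rank tests, Cucconi and
# Podgor-Gastwirth. The Cucconi statistic C combines the standardised sum of
# squared ranks (U) and squared contrary ranks (V) of one sample with their
# null correlation rho:
#   C = (U^2 + V^2 - 2 rho U V) / (2 (1 - rho^2)),
#   rho = 2 (N^2 - 4) / ((2N + 1)(8N + 11)) - 1,
# and has asymptotic null survival function P(C > c) = exp(-c). The
# Podgor-Gastwirth statistic S is the F statistic of the OLS regression of
# the sample-membership indicator on the midranks and squared midranks of
# the pooled data, referred to an F(2, N-3) null. Both rank tests also offer
# a label-permutation p-value; ties are handled by midranks throughout.

new_two_sample_test <- function(method, statistic, p.value, n1, n2,
                                p_method, stat_name) {
  structure(list(method = method, statistic = statistic, p.value = p.value,
                 n1 = n1, n2 = n2, p_method = p_method,
                 stat_name = stat_name),
            class = "two_sample_test")
}

#' @export
print.two_sample_test <- function(x, ...) {
  cat(sprintf("%s test: %s = %.4f, p = %.4g (%s, n = %d + %d)\n",
              x$method, x$stat_name, x$statistic, x$p.value, x$p_method,
              x$n1, x$n2))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] returning the sup-distance D
#' between the two empirical CDFs and the two-sided p-value.
#'
#' @param x,y numeric samples.
#' @return a `two_sample_test` object.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(x, y))
  new_two_sample_test("Kolmogorov-Smirnov", unname(kt$statistic),
                      kt$p.value, length(x), length(y),
                      if (grepl("exact", kt$method, ignore.case = TRUE))
                        "exact" else "asymptotic", "D")
}

# C statistic from pooled midranks; idx selects the first sample
cucconi_stat <- function(r, idx, n1, n2) {
  N <- n1 + n2
  rr <- r[idx]
  num <- (N + 1) * (2 * N + 1)
  den <- sqrt(n1 * n2 * (N + 1) * (2 * N + 1) * (8 * N + 11) / 5)
  U <- (6 * sum(rr^2) - n1 * num) / den
  V <- (6 * sum((N + 1 - rr)^2) - n1 * num) / den
  rho <- 2 * (N^2 - 4) / ((2 * N + 1) * (8 * N + 11)) - 1
  (U^2 + V^2 - 2 * rho * U * V) / (2 * (1 - rho^2))
}

#' Cucconi location-scale rank test
#'
#' @param x,y numeric samples (combined size at least 4).
#' @param p_method `"permutation"` (default) or `"asymptotic"`
#'   (`P(C > c) = exp(-c)`).
#' @param B number of label permutations.
#' @return a `two_sample_test` object.
#' @export
cucconi_test <- function(x, y, p_method = c("permutation", "asymptotic"),
                         B = 9999L) {
  p_method <- match.arg(p_method)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (N < 4L) stop("combined sample size must be at least 4")
  z <- c(x, y)
  if (length(unique(z)) < 2L) stop("degenerate samples: all values tied")
  r <- rank(z)
  C <- cucconi_stat(r, seq_len(n1), n1, n2)
  if (p_method == "asymptotic") {
    p <- exp(-C)
  } else {
    exceed <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(N, n1)
      if (cucconi_stat(r, idx, n1, n2) >= C) exceed <- exceed + 1L
    }
    p <- (exceed + 1L) / (B + 1L)
  }
  new_two_sample_test("Cucconi", C, p, n1, n2, p_method, "C")
}

# PG F statistic given design pieces; qx = qr of cbind(1, r, r^2)
pg_stat <- function(qx, ind, N) {
  eff <- qr.qty(qx, ind)[seq_len(qx$rank)]
  sse <- sum(ind^2) - sum(eff^2)
  sst <- sum((ind - mean(ind))^2)
  if (sse <= 0) sse <- .Machine$double.eps
  ((sst - sse) / 2) / (sse / (N - 3))
}

#' Podgor-Gastwirth efficiency-robust location-scale test
#'
#' Regresses the sample-membership indicator on the pooled midranks and
#' their squares; the test statistic S is the regression F statistic with
#' (2, N - 3) degrees of freedom.
#'
#' @inheritParams cucconi_test
#' @return a `two_sample_test` object.
#' @export
podgor_gastwirth_test <- function(x, y,
                                  p_method = c("permutation", "asymptotic"),
                                  B = 9999L) {
  p_method <- match.arg(p_method)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (N < 4L) stop("combined sample size must be at least 4")
  z <- c(x, y)
  if (length(unique(z)) < 2L) stop("degenerate samples: all values tied")
  r <- rank(z)
  X <- cbind(1, r, r^2)
  qx <- qr(X)
  ind <- c(rep(1, n1), rep(0, n2))
  S <- pg_stat(qx, ind, N)
  if (p_method == "asymptotic") {
    p <- stats::pf(S, 2, N - 3, lower.tail = FALSE)
  } else {
    exceed <- 0L
    for (b in seq_len(B)) {
      if (pg_stat(qx, sample(ind), N) >= S) exceed <- exceed + 1L
    }
    p <- (exceed + 1L) / (B + 1L)
  }
  new_two_sample_test("Podgor-Gastwirth", S, p, n1, n2, p_method, "S")
}

#' Tukey box-plot summary per group
#'
#' Mean, quartiles, 1.5*IQR whiskers and outlier count for each group.
#'
#' @param x numeric values.
#' @param group grouping vector.
#' @return a data frame with one row per group.
#' @export
boxplot_summary <- function(x, group) {
  groups <- sort(unique(as.character(group)))
  rows <- lapply(groups, function(g) {
    v <- x[group == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    data.frame(group = g, n = length(v), mean = mean(v),
               q1 = q[1], median = q[2], q3 = q[3],
               whisker_low = min(v[v >= lo]), whisker_high = max(v[v <= hi]),
               n_outliers = sum(v < lo | v > hi))
  })
  do.call(rbind, rows)
}

#' Compare one statistic between structured and non-structured trees
#'
#' Runs the Kolmogorov-Smirnov, Cucconi and Podgor-Gastwirth tests on one
#' statistic column of a [tree_stats_table()] split by its label column,
#' and summarises each group's distribution.
#'
#' @param stats_table data frame from [tree_stats_table()].
#' @param statistic name of the statistic column to compare.
#' @param group_col name of the label column (two groups required; the
#'   first group in sort order is taken as sample 1).
#' @param p_method p-value mode for the rank tests.
#' @param B permutation count when `p_method = "permutation"`.
#' @return a list with elements `statistic`, `tests` (list of
#'   `two_sample_test`) and `groups` (box-plot summary data frame).
#' @export
compare_populations <- function(stats_table, statistic,
                                group_col = "label",
                                p_method = c("asymptotic", "permutation"),
                                B = 9999L) {
  p_method <- match.arg(p_method)
  if (!statistic %in% names(stats_table)) stop("unknown statistic column")
  g <- as.character(stats_table[[group_col]])
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("exactly two labelled groups are required")
  x <- stats_table[[statistic]][g == lev[1]]
  y <- stats_table[[statistic]][g == lev[2]]
  tests <- list(
    ks = ks_two_sample(x, y),
    cucconi = cucconi_test(x, y, p_method = p_method, B = B),
    podgor_gastwirth = podgor_gastwirth_test(x, y, p_method = p_method,
                                             B = B))
  list(statistic = statistic, tests = tests,
       groups = boxplot_summary(stats_table[[statistic]], g))
}

#' Full comparison report over the eight statistics
#'
#' @inheritParams compare_populations
#' @param statistics statistic columns to compare; defaults to the eight
#'   classifier features.
#' @return a data frame with one row per statistic: D and its p-value,
#'   C and its p-value, S and its p-value, and the p-value mode used.
#' @export
comparison_report <- function(stats_table, statistics = feature_columns(),
                              group_col = "label",
                              p_method = c("asymptotic", "permutation"),
                              B = 9999L) {
  p_method <- match.arg(p_method)
  rows <- lapply(statistics, function(s) {
    cp <- compare_populations(stats_table, s, group_col, p_method, B)
    data.frame(statistic = s,
               D = cp$tests$ks$statistic, D_p = cp$tests$ks$p.value,
               C = cp$tests$cucconi$statistic,
               C_p = cp$tests$cucconi$p.value,
               S = cp$tests$podgor_gastwirth$statistic,
               S_p = cp$tests$podgor_gastwirth$p.value,
               p_method = p_method)
  })
  do.call(rbind, rows)
}
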