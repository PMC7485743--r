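# Statistical primitives shared by all pipeline stages. Exact null
# distributions are computed by generating-function / subset-sum dynamic
# programming, which is arithmetically identical to full enumeration of
# sign patterns (signed-rank) or rank splits (rank-sum).

#' Hypothesis test result
#'
#' Lightweight container for every test the pipeline runs.
#'
#' @param statistic Test statistic.
#' @param p_value P-value in `[0, 1]`.
#' @param alternative One of `"greater"`, `"less"`, `"two_sided"`.
#' @param method Human-readable description, including whether the exact
#'   or approximate null was used.
#' @param exact `TRUE` only when the null distribution was fully
#'   enumerated.
#'
#' @return An object of class `test_result`.
#' @export
test_result <- function(statistic, p_value, alternative, method, exact) {
  stopifnot(is.numeric(p_value), length(p_value) == 1L,
            p_value >= -1e-12, p_value <= 1 + 1e-12)
  structure(
    list(statistic = as.numeric(statistic),
         p_value = min(max(as.numeric(p_value), 0), 1),
         alternative = match.arg(alternative,
                                 c("greater", "less", "two_sided")),
         method = method,
         exact = isTRUE(exact)),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n",
      "statistic = ", format(x$statistic), ", p = ", format(x$p_value),
      " (", x$alternative, if (x$exact) ", exact" else ", approximate",
      ")\n", sep = "")
  invisible(x)
}

.match_alt <- function(alternative) {
  match.arg(alternative, c("greater", "less", "two_sided"))
}

# Exact distribution of the positive-rank sum W+ for (mid)ranks r:
# counts[k + 1] = number of sign patterns with 2*W+ = k. Midranks are
# multiples of 1/2, so doubling makes all exponents integral.
.signrank_counts <- function(r) {
  e <- as.integer(round(2 * r))
  total <- sum(e)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (ei in e) {
    shifted <- c(numeric(ei), counts[seq_len(total + 1L - ei)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped before ranking (Wilcoxon's original
#' convention). For `n <= 25` nonzero differences the null of the
#' positive-rank sum is fully enumerated (ties handled exactly through
#' midranks); larger samples use the normal approximation with tie
#' correction and no continuity correction.
#'
#' @param differences Numeric vector of paired differences.
#' @param alternative `"greater"` tests for positive shift, `"less"` for
#'   negative, `"two_sided"` for either.
#' @param exact_max Largest `n` for which the exact null is used.
#'
#' @return A [test_result]; `statistic` is the positive-rank sum W+.
#' @export
wilcoxon_signed_rank <- function(differences,
                                 alternative = c("greater", "less",
                                                 "two_sided"),
                                 exact_max = 25L) {
  alternative <- .match_alt(alternative)
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate paired sample: all differences zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    counts <- .signrank_counts(r)
    tot <- 2^n
    k <- as.integer(round(2 * w))
    idx <- seq_along(counts) - 1L
    p_ge <- sum(counts[idx >= k]) / tot
    p_le <- sum(counts[idx <= k]) / tot
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two_sided = min(1, 2 * min(p_ge, p_le)))
    return(test_result(w, p, alternative,
                       "Wilcoxon signed-rank test (exact)", TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) {
    return(test_result(w, 1, alternative,
                       "Wilcoxon signed-rank test (degenerate)", FALSE))
  }
  z <- (w - mu) / sqrt(sigma2)
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two_sided = 2 * stats::pnorm(-abs(z)))
  test_result(w, min(p, 1), alternative,
              "Wilcoxon signed-rank test (normal approximation)", FALSE)
}

# Number of size-k subsets of ranks 1..n with each possible sum;
# dp[k + 1, s + 1] after the loop.
.ranksum_counts <- function(n, k) {
  smax <- sum(seq_len(n)) # upper bound on any subset sum
  dp <- matrix(0, nrow = k + 1L, ncol = smax + 1L)
  dp[1L, 1L] <- 1
  for (v in seq_len(n)) {
    for (kk in rev(seq_len(min(v, k)))) {
      src <- dp[kk, seq_len(smax + 1L - v)]
      dp[kk + 1L, (v + 1L):(smax + 1L)] <-
        dp[kk + 1L, (v + 1L):(smax + 1L)] + src
    }
  }
  dp[k + 1L, ]
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact when the pooled sample size is at most `exact_max` and no ties
#' are present (the null over all rank splits is fully enumerated);
#' otherwise normal approximation with tie correction, no continuity
#' correction.
#'
#' @param x,y Numeric samples.
#' @param alternative `"less"` tests whether `x` tends to be smaller
#'   than `y`.
#' @param exact_max Largest pooled size for the exact null.
#'
#' @return A [test_result]; `statistic` is the rank sum of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("greater", "less",
                                              "two_sided"),
                              exact_max = 20L) {
  alternative <- .match_alt(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(pooled) > 0L
  if (n <= exact_max && !ties) {
    counts <- .ranksum_counts(n, nx)
    tot <- choose(n, nx)
    s <- seq_along(counts) - 1L
    p_ge <- sum(counts[s >= w]) / tot
    p_le <- sum(counts[s <= w]) / tot
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two_sided = min(1, 2 * min(p_ge, p_le)))
    return(test_result(w, p, alternative,
                       "Wilcoxon rank-sum test (exact)", TRUE))
  }
  mu <- nx * (n + 1) / 2
  tie_tab <- table(pooled)
  sigma2 <- nx * ny / 12 *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(test_result(w, 1, alternative,
                       "Wilcoxon rank-sum test (degenerate)", FALSE))
  }
  z <- (w - mu) / sqrt(sigma2)
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two_sided = 2 * stats::pnorm(-abs(z)))
  test_result(w, min(p, 1), alternative,
              "Wilcoxon rank-sum test (normal approximation)", FALSE)
}

# log hypergeometric point mass for x successes given margins
.lhyper <- function(x, r1, r2, c1) {
  lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1)
}

#' Fisher exact test for a 2x2 contingency table
#'
#' One-sided p-values are exact hypergeometric tail sums on the `[1,1]`
#' cell; the two-sided p-value sums all tables (same margins) whose
#' probability does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of nonnegative integers.
#' @param alternative `"greater"` puts the alternative on enrichment of
#'   the `[1,1]` cell.
#'
#' @return A [test_result]; `statistic` is the `[1,1]` cell count.
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("greater", "less",
                                             "two_sided")) {
  alternative <- .match_alt(alternative)
  tab <- as.matrix(table)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0)) stop("negative cell in 2x2 table")
  if (any(abs(tab - round(tab)) > 1e-8)) stop("non-integer cell count")
  tab <- round(tab)
  if (sum(tab) == 0) stop("all margins zero")
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  dens <- exp(.lhyper(xs, r1, r2, c1))
  dens <- dens / sum(dens) # guard rounding
  p <- switch(alternative,
              greater = sum(dens[xs >= a]),
              less = sum(dens[xs <= a]),
              two_sided = sum(dens[dens <= dens[xs == a] * (1 + 1e-7)]))
  test_result(a, min(p, 1), alternative, "Fisher exact test (2x2)", TRUE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) m / j`, returned in
#' input order and capped at 1. `NA` entries are carried through and do
#' not count toward `m`.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#'
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-value outside [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0L) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    q <- pmin(1, cummin(pv[o] * m / (m - seq_len(m) + 1L)))[ro]
    out[ok] <- q
  }
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic is the supremum distance between the two empirical CDFs;
#' the p-value uses the asymptotic Kolmogorov distribution evaluated at
#' `sqrt(nx * ny / (nx + ny)) * D`.
#'
#' @param x,y Numeric samples.
#'
#' @return A [test_result] with the D statistic.
#' @export
ks_2samp <- function(x, y) {
  x <- sort(x[!is.na(x)]); y <- sort(y[!is.na(y)])
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("empty sample")
  pts <- sort(unique(c(x, y)))
  fx <- stats::stepfun(x, c(0, seq_len(nx) / nx))(pts)
  fy <- stats::stepfun(y, c(0, seq_len(ny) / ny))(pts)
  d <- max(abs(fx - fy))
  t <- sqrt(nx * ny / (nx + ny)) * d
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  test_result(d, min(max(p, 0), 1), "two_sided",
              "Two-sample Kolmogorov-Smirnov test (asymptotic)", FALSE)
}

#' Pearson chi-square test for a 2x2 table
#'
#' No continuity correction, one degree of freedom.
#'
#' @param table 2x2 matrix of nonnegative counts.
#'
#' @return A [test_result] with the chi-square statistic.
#' @export
chi2_2x2 <- function(table) {
  tab <- as.matrix(table)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0)) stop("negative cell in 2x2 table")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("undefined expected counts: zero margin")
  }
  stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (rs[1] * rs[2] * cs[1] * cs[2])
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  test_result(stat, p, "two_sided",
              "Pearson chi-square test (2x2, df = 1)", FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (tie-aware).
#'
#' @param x,y Equal-length numeric vectors, length at least 3.
#'
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) stop("undefined correlation: constant vector")
  sum(dx * dy) / (sx * sy)
}

#' Highest density interval of an empirical sample
#'
#' Shortest contiguous window over the sorted sample containing
#' `ceiling(mass * n)` points; ties in width are broken toward the
#' smallest lower bound. No density smoothing is applied.
#'
#' @param sample Numeric vector, length at least 2.
#' @param mass Probability mass in `(0, 1]` (default 0.95).
#'
#' @return A list of class `interval` with `lower`, `upper`, `mass`.
#' @export
hdi <- function(sample, mass = 0.95) {
  s <- sort(sample[!is.na(sample)])
  n <- length(s)
  if (n == 0L) stop("empty sample")
  if (n < 2L) stop("need at least 2 points for an HDI")
  if (!(mass > 0 && mass <= 1)) stop("mass must be in (0, 1]")
  k <- ceiling(mass * n)
  nwin <- n - k + 1L
  widths <- s[k:n] - s[seq_len(nwin)]
  # ties (within float rounding of the subtractions) break toward the
  # smallest lower bound
  eps <- 4 * .Machine$double.eps * max(abs(s[1]), abs(s[n]), 1)
  i <- which(widths <= min(widths) + eps)[1L]
  structure(list(lower = s[i], upper = s[i + k - 1L], mass = mass),
            class = "interval")
}

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("%.0f%% HDI: [%g, %g]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}
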