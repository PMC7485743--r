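# Statistical primitives: frozen worked examples, brute-force
# enumeration oracles, base-R cross-checks and degenerate inputs.

test_that("signed-rank worked examples and degenerate input", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), "greater")$p_value,
               0.125)
  expect_equal(wilcoxon_signed_rank(c(-1, -2, -3), "greater")$p_value,
               1.0)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0), "greater"),
               "degenerate")
  # zeros dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 1, 2, 3), "greater")$p_value,
               0.125)
  r <- wilcoxon_signed_rank(c(1, 2, 3), "greater")
  expect_true(r$exact)
})

test_that("signed-rank matches sign-pattern enumeration (with ties)", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE) # ties guaranteed
    for (alt in c("greater", "less", "two_sided")) {
      expect_equal(wilcoxon_signed_rank(d, alt)$p_value,
                   oracle_signrank(d, alt),
                   tolerance = 1e-12,
                   info = paste("n =", n, "alt =", alt))
    }
  }
})

test_that("signed-rank agrees with wilcox.test on continuous data", {
  set.seed(42)
  d_small <- rnorm(15)
  expect_equal(wilcoxon_signed_rank(d_small, "two_sided")$p_value,
               wilcox.test(d_small, exact = TRUE)$p.value)
  d_big <- rnorm(40)
  expect_equal(
    wilcoxon_signed_rank(d_big, "greater")$p_value,
    wilcox.test(d_big, alternative = "greater", exact = FALSE,
                correct = FALSE)$p.value)
})

test_that("rank-sum worked examples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), "less")$p_value,
               1 / 6)
  expect_equal(wilcoxon_rank_sum(c(3, 4), c(1, 2), "less")$p_value, 1)
  expect_equal(
    wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5), "two_sided")$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("rank-sum matches rank-split enumeration and wilcox.test", {
  set.seed(43)
  for (i in 1:20) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    for (alt in c("greater", "less", "two_sided")) {
      expect_equal(wilcoxon_rank_sum(x, y, alt)$p_value,
                   oracle_ranksum(x, y, alt), tolerance = 1e-12)
    }
  }
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(wilcoxon_rank_sum(x, y, "two_sided")$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)
  # tied data fall back to the tie-corrected normal approximation
  xt <- rep(1:4, 3); yt <- rep(2:5, 3)
  expect_equal(
    wilcoxon_rank_sum(xt, yt, "two_sided")$p_value,
    wilcox.test(xt, yt, exact = FALSE, correct = FALSE)$p.value)
})

test_that("Fisher exact worked examples and oracle equivalence", {
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3)),
                                "greater")$p_value, 17 / 70)
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5)),
                                "greater")$p_value, 1 / 252)
  expect_equal(fisher_exact_2x2(rbind(c(1, 1), c(1, 1)),
                                "two_sided")$p_value, 1)
  expect_error(fisher_exact_2x2(rbind(c(-1, 1), c(1, 1))), "negative")
  set.seed(44)
  for (i in 1:25) {
    tab <- matrix(sample(0:4, 4, replace = TRUE), 2)
    if (sum(tab) == 0 || sum(tab[1, ]) == 0 || sum(tab[, 1]) == 0) next
    expect_equal(fisher_exact_2x2(tab, "greater")$p_value,
                 oracle_fisher_greater(tab), tolerance = 1e-10)
    expect_equal(fisher_exact_2x2(tab, "two_sided")$p_value,
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment: worked examples, p.adjust, permutations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  set.seed(45)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("KS two-sample: examples and ks.test agreement", {
  expect_equal(ks_2samp(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_2samp(c(1, 2), c(3, 4))$statistic, 1)
  expect_equal(ks_2samp(c(1, 3), c(2, 4))$statistic, 0.5)
  expect_error(ks_2samp(numeric(0), 1), "empty")
  set.seed(46)
  x <- rnorm(60); y <- rnorm(80, 0.3)
  ref <- suppressWarnings(ks.test(x, y, exact = FALSE))
  mine <- ks_2samp(x, y)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("chi-square 2x2: examples and chisq.test agreement", {
  r <- chi2_2x2(rbind(c(10, 10), c(10, 10)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(chi2_2x2(rbind(c(20, 10), c(10, 20)))$statistic,
               20 / 3, tolerance = 1e-12)
  expect_error(chi2_2x2(rbind(c(1, 0), c(0, 0))), "margin")
  set.seed(47)
  tab <- matrix(rpois(4, 30) + 1, 2)
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(chi2_2x2(tab)$statistic, unname(ref$statistic))
  expect_equal(chi2_2x2(tab)$p_value, ref$p.value)
})

test_that("Spearman rho: examples, ties, cor agreement", {
  expect_equal(spearman_rho(1:5, 2 * (1:5) + 3), 1)
  expect_equal(spearman_rho(1:5, rev(1:5)), -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  set.seed(48)
  x <- sample(1:5, 30, replace = TRUE)
  y <- x + sample(1:3, 30, replace = TRUE)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
})

test_that("HDI: worked examples and exhaustive-scan oracle", {
  h <- hdi(seq(0.01, 0.20, by = 0.01), 0.95)
  expect_equal(h$lower, 0.01)
  expect_equal(h$upper, 0.19)
  hc <- hdi(rep(3, 10), 0.95)
  expect_equal(c(hc$lower, hc$upper), c(3, 3))
  x <- rnorm(50)
  h1 <- hdi(x, 1.0)
  expect_equal(c(h1$lower, h1$upper), range(x))
  expect_error(hdi(numeric(0)), "empty")
  set.seed(49)
  for (i in 1:50) {
    n <- sample(2:500, 1)
    x <- switch(sample(3, 1), runif(n), rbeta(n, 0.5, 3),
                sample(seq(0, 1, 0.05), n, replace = TRUE))
    m <- runif(1, 0.05, 1)
    mine <- hdi(x, m)
    ora <- oracle_hdi(x, m)
    expect_equal(mine$upper - mine$lower, ora$w, tolerance = 1e-12)
    expect_equal(mine$lower, ora$lower)
  }
})

test_that("continuous-data tests hold their nominal type-I error", {
  set.seed(50)
  B <- 4000
  # signed-rank, n = 20 (exact null precomputed once: no ties)
  p_sr <- replicate(B, wilcoxon_signed_rank(rnorm(20),
                                            "two_sided")$p_value)
  expect_gt(mean(p_sr <= 0.05), 0.03)
  expect_lt(mean(p_sr <= 0.05), 0.07)
  # rank-sum, 12 vs 12 (normal approximation)
  p_rs <- replicate(B, wilcoxon_rank_sum(rnorm(12), rnorm(12),
                                         "two_sided")$p_value)
  expect_gt(mean(p_rs <= 0.05), 0.03)
  expect_lt(mean(p_rs <= 0.05), 0.07)
})
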