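# Independent brute-force oracles used to pin down the package's exact
# tests. These deliberately use naive full enumeration, not the
# package's dynamic-programming code paths.

# Signed-rank: enumerate all 2^n sign assignments over the midranks of
# |d| and count patterns with W+ at least / at most the observed one.
oracle_signrank <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

# Rank-sum: enumerate all choose(n, nx) assignments of ranks to x.
oracle_ranksum <- function(x, y, alternative) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  splits <- utils::combn(n, nx)
  w_all <- apply(splits, 2, function(i) sum(r[i]))
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

# Hypergeometric upper tail by enumerating every size-n subset of a
# labelled universe and counting overlaps with the term set.
oracle_hyper_upper <- function(k, term_size, universe, draw) {
  subsets <- utils::combn(universe, draw)
  overlaps <- colSums(subsets <= term_size) # term = items 1..term_size
  mean(overlaps >= k)
}

# Fisher one-sided greater via the same subset enumeration.
oracle_fisher_greater <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  oracle_hyper_upper(tab[1, 1], r1, n, c1)
}

# HDI by exhaustive scan over every contiguous window of the sorted
# sample.
oracle_hdi <- function(x, mass) {
  s <- sort(x)
  n <- length(s)
  k <- ceiling(mass * n)
  eps <- 4 * .Machine$double.eps * max(abs(s[1]), abs(s[n]), 1)
  best <- NULL
  for (i in seq_len(n - k + 1)) {
    w <- s[i + k - 1] - s[i]
    if (is.null(best) || w < best$w - eps) {
      best <- list(w = w, lower = s[i], upper = s[i + k - 1])
    }
  }
  best
}

# Balanced-ANOVA method-of-moments variance fractions (truncation at
# zero), the closed-form oracle for the REML fits.
oracle_mom_fractions <- function(y, species, sex) {
  ms <- suppressWarnings(
    stats::anova(stats::lm(y ~ factor(species) + factor(sex))))[["Mean Sq"]]
  sa <- max(0, (ms[1] - ms[3]) / mean(table(species)))
  sb <- max(0, (ms[2] - ms[3]) / mean(table(sex)))
  tot <- sa + sb + ms[3]
  c(species = sa / tot, sex = sb / tot, residual = ms[3] / tot)
}

# NG86 site counts by direct mutation enumeration with the translation
# table, independent of the package's cached lookup arrays.
oracle_ng86_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  base <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    for (nt in setdiff(nts, base[p])) {
      mut <- base
      mut[p] <- nt
      mutc <- paste(mut, collapse = "")
      if (code[[mutc]] != "*" && code[[mutc]] == code[[codon]]) {
        s <- s + 1 / 3
      }
    }
  }
  c(S = s, N = 3 - s)
}

# NG86 substitution counts by explicit path enumeration over position
# orderings (recursive, string-based).
oracle_ng86_sub <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  diffs <- which(av != bv)
  if (length(diffs) == 0) return(c(Sd = 0, Nd = 0))
  perms <- if (length(diffs) == 1) list(diffs) else {
    pm <- gtools_permutations(length(diffs))
    lapply(seq_len(nrow(pm)), function(i) diffs[pm[i, ]])
  }
  res <- lapply(perms, function(ord) {
    cur <- av
    syn <- 0; non <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- bv[pos]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*") blocked <- TRUE
      if (aa1 == aa2 && aa1 != "*") syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    list(counts = c(syn, non), blocked = blocked)
  })
  blocked <- vapply(res, `[[`, logical(1), "blocked")
  use <- if (all(blocked)) res else res[!blocked]
  m <- colMeans(do.call(rbind, lapply(use, `[[`, "counts")))
  c(Sd = m[1], Nd = m[2])
}

# All permutations of 1..n (small n), avoiding extra dependencies.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Small ready-made expression study with planted structure.
make_test_study <- function(n_genes = 120, frac_species = 0,
                            direction = "none", sd_total = 0.7,
                            seed = 1, n_per_species = 8,
                            baseline_sd = 2) {
  set.seed(seed + 5000)
  truth <- expression_truth(
    sprintf("g%04d", seq_len(n_genes)),
    baseline_log2 = rnorm(n_genes, 5, baseline_sd),
    frac_species = frac_species,
    frac_residual = 1 - frac_species,
    species_direction = direction,
    sd_total = sd_total)
  design <- sample_design(n_per_species)
  sim <- simulate_counts(truth, design, seed = seed)
  study <- expression_study(sim$counts, as.data.frame(design))
  list(study = normalize_log(filter_unexpressed(study)),
       sim = sim, truth = truth, design = design)
}
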