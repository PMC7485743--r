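# Expression module: filtering semantics, the TMM contract (with edgeR
# as the independent reference), normalization arithmetic, correlation
# structure, rank-based DE and the association tests.

test_that("filter_unexpressed implements the both-species-silent rule", {
  counts <- rbind(allzero = rep(0L, 8),
                  a_only = c(5, 3, 2, 1, 0, 0, 0, 0),
                  b_only = c(0, 0, 0, 0, 2, 2, 1, 4),
                  both = c(1:8))
  colnames(counts) <- paste0("s", 1:8)
  samples <- data.frame(sample_id = paste0("s", 1:8),
                        species = rep(c("A", "B"), each = 4),
                        sex = rep(c("F", "M"), 4))
  st <- expression_study(counts, samples)
  f_and <- filter_unexpressed(st, "and")
  expect_setequal(rownames(f_and$counts), c("a_only", "b_only", "both"))
  f_or <- filter_unexpressed(st, "or")
  expect_setequal(rownames(f_or$counts), "both")
  # idempotent, and library sizes recomputed from the filtered matrix
  expect_identical(filter_unexpressed(f_and, "and")$counts,
                   f_and$counts)
  expect_equal(unname(f_and$lib_size), unname(colSums(f_and$counts)))
})

test_that("TMM factors: replicates, depth scaling, half-doubled", {
  set.seed(61)
  mu <- rlnorm(1500, log(150), 1)
  base <- rpois(1500, mu)
  ident <- cbind(a = base, b = base)
  rownames(ident) <- paste0("g", 1:1500)
  expect_equal(unname(tmm_factors(ident)), c(1, 1), tolerance = 1e-6)
  scaled <- cbind(a = base, b = 3L * base)
  rownames(scaled) <- rownames(ident)
  expect_equal(unname(tmm_factors(scaled)), c(1, 1), tolerance = 1e-6)
  # half the genes doubled in sample 2, equal nominal library sizes:
  # the trimmed mean M sits midway, factor ratio ~ sqrt(2)
  dbl <- rep(c(2, 1), each = 750)
  cc <- cbind(x = rpois(1500, mu), y = rpois(1500, mu * dbl))
  rownames(cc) <- rownames(ident)
  f <- tmm_factors(cc, lib_size = c(1e6, 1e6))
  expect_equal(unname(f[2] / f[1]), sqrt(2), tolerance = 0.05)
  expect_error(tmm_factors(ident[, 1, drop = FALSE]), "2 samples")
})

test_that("TMM matches edgeR::calcNormFactors on random matrices", {
  skip_if_not_installed("edgeR")
  set.seed(62)
  for (i in 1:3) {
    mu <- rlnorm(800, log(100), 1.2)
    counts <- sapply(1:6, function(j) {
      rpois(800, mu * exp(rnorm(800, 0, 0.15)) * runif(1, 0.5, 2))
    })
    dimnames(counts) <- list(paste0("g", 1:800), paste0("s", 1:6))
    expect_equal(unname(tmm_factors(counts)),
                 unname(edgeR::calcNormFactors(counts,
                                               method = "TMM")),
                 tolerance = 1e-10)
  }
})

test_that("normalize_log arithmetic and scaling invariance", {
  counts <- rbind(g1 = c(999L, 500L, 400L, 300L),
                  g2 = c(0L, 100L, 50L, 20L),
                  g3 = c(300L, 200L, 100L, 250L))
  colnames(counts) <- paste0("s", 1:4)
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        species = c("A", "A", "B", "B"),
                        sex = c("F", "M", "F", "M"))
  # direct check of the log2-CPM formula
  st <- expression_study(rbind(counts, matrix(100L, 50, 4,
    dimnames = list(paste0("f", 1:50), paste0("s", 1:4)))), samples)
  st$lib_size <- rep(1e6, 4)
  st <- normalize_log(st)
  expect_equal(unname(st$normalized["g2", 1]), 0) # zero count -> 0
  expect_equal(unname(st$normalized["g1", 1]),
               log2(999 / (1e6 * st$tmm_factor[[1]]) * 1e6 + 1))
  # multiplying one sample by a constant leaves normalized expression
  # exactly unchanged for the unweighted trimmed mean, and unchanged
  # up to the depth-dependent precision weights for the default
  big <- make_test_study(n_genes = 300, seed = 9)$study
  counts2 <- big$counts
  counts2[, 3] <- counts2[, 3] * 5
  f_unw1 <- tmm_factors(big$counts, do_weighting = FALSE)
  f_unw2 <- tmm_factors(counts2, do_weighting = FALSE)
  expect_equal(f_unw1, f_unw2, tolerance = 1e-10)
  st2 <- normalize_log(expression_study(counts2, big$samples))
  expect_equal(st2$normalized, big$normalized, tolerance = 0.01)
})

test_that("correlation structure separates intra from inter species", {
  ts <- make_test_study(n_genes = 400, frac_species = 0.5,
                        direction = "none", seed = 12)
  ca <- correlation_analysis(ts$study)
  expect_equal(ca$matrix, t(ca$matrix))
  expect_equal(unname(diag(ca$matrix)), rep(1, 16))
  expect_length(ca$intra, 2 * choose(8, 2))
  expect_length(ca$inter, 64)
  expect_gt(ca$median_intra, ca$median_inter)
  expect_lt(ca$test$p_value, 0.01)
})

test_that("differential expression: planted effect and edge cases", {
  # 5 genes with a +8 log2 species shift against a null background:
  # complete separation gives the minimal achievable exact two-sided
  # rank-sum p at 8 vs 8, 2 / choose(16, 8)
  n <- 200
  ids <- sprintf("g%03d", 1:n)
  truth <- expression_truth(
    ids, baseline_log2 = rnorm(n, 6, 1.5),
    frac_species = c(rep(1, 5), rep(0, n - 5)),
    frac_sex = 0,
    frac_residual = c(rep(0, 5), rep(1, n - 5)),
    species_direction = c(rep("up_in_A", 5), rep("none", n - 5)),
    sd_total = c(rep(4 * sqrt(2), 5), rep(0.5, n - 5)))
  sim <- simulate_counts(truth, sample_design(), seed = 13)
  st <- normalize_log(filter_unexpressed(
    expression_study(sim$counts, as.data.frame(sample_design()))))
  de <- differential_expression(st)
  planted <- de[match(ids[1:5], de$gene_id), ]
  expect_equal(planted$p, rep(2 / choose(16, 8), 5),
               tolerance = 1e-12)
  expect_true(all(planted$log2fc > 4))
  expect_true(all(planted$is_DEG))
  expect_false(any(de$is_DEG[match(ids[50:200], de$gene_id)]))
})

test_that("DE p-values are well calibrated under the null", {
  ts <- make_test_study(n_genes = 1500, frac_species = 0, seed = 14)
  de <- differential_expression(ts$study)
  expect_lt(mean(de$p < 0.05), 0.07)
  # super-uniform or uniform: one-sided KS against the anti-
  # conservative direction
  ks <- suppressWarnings(ks.test(de$p, "punif",
                                 alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(sum(de$is_DEG) / nrow(de), 0.02)
})

test_that("selection-expression association runs and errors properly", {
  ts <- make_test_study(n_genes = 120, frac_species = 0.3,
                        direction = "none", seed = 15)
  de <- differential_expression(ts$study)
  genes <- de$gene_id
  aln <- lapply(seq_along(genes), function(i) {
    simulate_codon_pair(120, if (i <= 3) 3 else 0.2, 0.2,
                        seed = 9000 + i, gene_id = genes[i])
  })
  kaks <- selection_scan(aln)
  assoc <- selection_expression_association(de, kaks)
  expect_true(assoc$ks$p_value >= 0 && assoc$ks$p_value <= 1)
  expect_true(assoc$chi2$p_value >= 0 && assoc$chi2$p_value <= 1)
  expect_equal(sum(assoc$table), length(genes))
  de_all <- de
  de_all$is_DEG <- TRUE # every gene DEG -> empty stratum
  expect_error(selection_expression_association(de_all, kaks),
               "empty stratum")
})

test_that("count matrix TSV round-trips", {
  ts <- make_test_study(n_genes = 30, seed = 16)
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(ts$sim$counts, path)
  back <- read_counts(path)
  expect_equal(back, ts$sim$counts)
})
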