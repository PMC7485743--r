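# NG86 counting, Jukes-Cantor correction, the per-gene Ka/Ks contract
# and the scan-level filters/classification.

test_that("ng86_sites worked examples", {
  expect_equal(ng86_sites("TTT")$S, 1 / 3)
  expect_equal(ng86_sites("TTT")$N, 8 / 3)
  expect_equal(ng86_sites("ATG")$S, 0)
  expect_equal(ng86_sites("GGG")$S, 1)
  expect_error(ng86_sites("TAA"), "stop")
  expect_error(ng86_sites("ANT"))
})

test_that("ng86_substitutions worked examples and symmetry", {
  expect_equal(ng86_substitutions("TTT", "TTT"), list(Sd = 0, Nd = 0))
  expect_equal(ng86_substitutions("TTT", "TTC"), list(Sd = 1, Nd = 0))
  expect_equal(ng86_substitutions("TTT", "GTA"),
               list(Sd = 0.5, Nd = 1.5))
  set.seed(31)
  tb_codons <- rownames(as.matrix(Biostrings::GENETIC_CODE))
  codons <- names(Biostrings::GENETIC_CODE)
  nonstop <- codons[Biostrings::GENETIC_CODE != "*"]
  for (i in 1:40) {
    a <- sample(nonstop, 1); b <- sample(nonstop, 1)
    ab <- ng86_substitutions(a, b)
    ba <- ng86_substitutions(b, a)
    expect_equal(ab$Sd, ba$Sd)
    expect_equal(ab$Nd, ba$Nd)
    nd <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(ab$Sd + ab$Nd, nd)
  }
})

test_that("site and substitution counts match the enumeration oracle", {
  codons <- names(Biostrings::GENETIC_CODE)
  nonstop <- codons[Biostrings::GENETIC_CODE != "*"]
  set.seed(32)
  for (cd in sample(nonstop, 12)) {
    ora <- oracle_ng86_sites(cd)
    expect_equal(ng86_sites(cd)$S, unname(ora["S"]), tolerance = 1e-12)
  }
  for (i in 1:15) {
    a <- sample(nonstop, 1); b <- sample(nonstop, 1)
    ora <- oracle_ng86_sub(a, b)
    mine <- ng86_substitutions(a, b)
    expect_equal(mine$Sd, unname(ora["Sd"]), tolerance = 1e-12)
    expect_equal(mine$Nd, unname(ora["Nd"]), tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction behaves at the boundaries", {
  expect_equal(jukes_cantor(0), 0)
  expect_true(is.na(jukes_cantor(0.75)))
  p <- seq(0, 0.74, 0.01)
  expect_true(all(diff(jukes_cantor(p)) > 0))
})

test_that("kaks_pair reproduces the 10-codon worked example", {
  al <- codon_alignment("ex", paste0("TTT", strrep("GGG", 9)),
                        paste0("TTC", strrep("GGG", 9)))
  r <- kaks_pair(al)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$S, 28 / 3, tolerance = 1e-12)
  expect_equal(r$N, 30 - 28 / 3, tolerance = 1e-12)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0.11561, tolerance = 1e-4)
  expect_equal(r$omega, 0)
})

test_that("kaks_pair handles identical, gapped and swapped input", {
  s <- "ATGGCTAAAGCT"
  ident <- kaks_pair(codon_alignment("i", s, s))
  expect_equal(ident$Ka, 0)
  expect_equal(ident$Ks, 0)
  expect_true(is.na(ident$omega))
  expect_true("undefined_ratio" %in% ident$filter_flags)
  # gapped codons excluded from the comparison
  g <- kaks_pair(codon_alignment("g", "ATG---AAAGCT", "ATGGCTAAAGCT"))
  expect_equal(g$compared_bp, 9L)
  expect_equal(g$S + g$N, 9)
  # invariant to swapping the sequences
  al <- simulate_codon_pair(300, 0.8, 0.2, seed = 5)
  r1 <- kaks_pair(al)
  r2 <- kaks_pair(codon_alignment(al$gene_id, al$seq_b, al$seq_a))
  expect_equal(r1$omega, r2$omega, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_error(kaks_pair(codon_alignment("x", "---", "---")),
               "no comparable")
})

test_that("site/substitution invariants hold on simulated genes", {
  for (i in 1:5) {
    al <- simulate_codon_pair(150, runif(1, 0.1, 2), 0.25, seed = i)
    r <- kaks_pair(al)
    expect_equal(r$S + r$N, r$compared_bp, tolerance = 1e-9)
    nt_diffs <- sum(strsplit(al$seq_a, "")[[1]] !=
                      strsplit(al$seq_b, "")[[1]])
    expect_equal(r$Sd + r$Nd, nt_diffs, tolerance = 1e-9)
  }
})

test_that("selection_scan filters and classifies", {
  set.seed(33)
  aln <- c(
    lapply(1:20, function(i) {
      simulate_codon_pair(150, 0.1, 0.2, seed = 400 + i,
                          gene_id = sprintf("null%02d", i))
    }),
    lapply(1:3, function(i) {
      simulate_codon_pair(500, 4, 0.3, seed = 500 + i,
                          gene_id = sprintf("pos%02d", i))
    }),
    list(simulate_codon_pair(20, 4, 0.3, seed = 600,
                             gene_id = "short01")))
  scan <- selection_scan(aln)
  pos <- scan$gene_id[scan$classification == "positive"]
  expect_setequal(pos, c("pos01", "pos02", "pos03"))
  short <- scan[scan$gene_id == "short01", ]
  expect_match(short$flags, "short_alignment")
  expect_false(short$classification == "positive")
  # omega < 1 everywhere -> no positive calls
  scan_null <- selection_scan(aln[1:20])
  expect_equal(sum(scan_null$classification == "positive"), 0)
  # low-coverage flag
  gap_seq <- paste0(strrep("-", 60), strrep("ATG", 60))
  cov <- selection_scan(list(codon_alignment(
    "cov", gap_seq, paste0(strrep("-", 60), strrep("ATG", 60)))))
  expect_match(cov$flags, "low_coverage")
})

test_that("planted high-omega genes rank on top of the scan", {
  aln <- c(
    lapply(1:40, function(i) {
      simulate_codon_pair(300, 0.1, 0.2, seed = 700 + i,
                          gene_id = sprintf("bg%03d", i))
    }),
    lapply(1:5, function(i) {
      simulate_codon_pair(400, 3, 0.2, seed = 800 + i,
                          gene_id = sprintf("hot%02d", i))
    }))
  scan <- selection_scan(aln)
  top5 <- scan$gene_id[order(-scan$omega)][1:5]
  expect_setequal(top5, sprintf("hot%02d", 1:5))
})

test_that("pairwise_species_scan assembles per-pair matrices", {
  mk <- function(g, om, seed) {
    simulate_codon_pair(300, om, 0.2, seed = seed, gene_id = g)
  }
  pairs <- list(
    "sp1|sp2" = list(mk("gA", 3, 1), mk("gB", 0.1, 2)),
    "sp1|sp3" = list(mk("gA", 0.1, 3), mk("gB", 0.1, 4)),
    "sp2|sp3" = list(mk("gB", 0.1, 5)))
  res <- pairwise_species_scan(pairs)
  expect_identical(dim(res$omega), c(2L, 3L))
  expect_true(is.na(res$omega["gA", "sp2|sp3"]))
  expect_true("gA" %in% res$psg[["sp1|sp2"]])
  expect_false("gA" %in% res$psg[["sp1|sp3"]])
  # k = 2 degenerates to a single selection_scan
  single <- pairwise_species_scan(pairs["sp1|sp2"])
  expect_identical(single$scans[[1]],
                   selection_scan(pairs[["sp1|sp2"]]))
})

test_that("alignment FASTA round-trips through read/write", {
  aln <- lapply(1:3, function(i) {
    simulate_codon_pair(50, 0.5, 0.2, seed = i,
                        gene_id = sprintf("g%02d", i),
                        species_a = "myotis", species_b = "molossus")
  })
  names(aln) <- vapply(aln, `[[`, character(1), "gene_id")
  path <- tempfile(fileext = ".fasta")
  write_codon_alignments(aln, path)
  back <- read_codon_alignments(path)
  expect_identical(back, aln)
  expect_error(codon_alignment("x", "ATGC", "ATGC"), "divisible")
  expect_error(codon_alignment("x", "ATG", "ATGGGG"), "equal")
  expect_error(codon_alignment("x", "ATN", "ATG"), "alphabet")
})
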