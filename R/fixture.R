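# Self-consistent synthetic dataset with planted signal in every
# pipeline stage, written as plain-text files.

#' Generate and write a complete synthetic study
#'
#' Emits a self-consistent dataset emulating the two-species,
#' 8-individuals-each, mixed-sex study design: pairwise codon
#' alignments with a handful of genes evolved under positive selection,
#' a count matrix with planted high-interspecific-variance genes, a
#' term annotation with one planted differentially expressed term, and
#' anti-/pro-longevity gene lists (the anti list planted with lower
#' expression in the long-lived species).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_genes Total genes (default 800).
#' @param n_psg Genes evolved at `omega_psg` (default 5).
#' @param n_screen Genes with species variance fraction
#'   `frac_screen` (default 100, half up in each species; 30 of the
#'   up-in-A ones form the planted term).
#' @param n_anti,n_pro Longevity list sizes (defaults 19 and 28).
#' @param n_terms Random annotation terms (default 50).
#' @param n_per_species Individuals per species (default 8).
#' @param omega_psg,omega_background Target Ka/Ks ratios (3 and 0.1).
#' @param divergence Target substitutions per site (default 0.2).
#' @param len_codons_psg,len_codons_background Alignment lengths in
#'   codons (500 and 200).
#' @param frac_screen Species variance fraction of planted screen
#'   genes (default 0.95).
#' @param library_size Expected depth per sample (default 3e6).
#'
#' @return Named list of file paths plus the ground-truth tables,
#'   invisibly.
#' @export
make_fixture <- function(dir, seed = 1L,
                         n_genes = 800L, n_psg = 5L, n_screen = 100L,
                         n_anti = 19L, n_pro = 28L, n_terms = 50L,
                         n_per_species = 8L,
                         omega_psg = 3, omega_background = 0.1,
                         divergence = 0.2,
                         len_codons_psg = 500L,
                         len_codons_background = 200L,
                         frac_screen = 0.95,
                         library_size = 3e6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  psg_genes <- genes[seq_len(n_psg)]

  # roles are disjoint gene blocks after the PSGs
  at <- n_psg
  screen_genes <- genes[at + seq_len(n_screen)]; at <- at + n_screen
  anti_genes <- genes[at + seq_len(n_anti)]; at <- at + n_anti
  pro_genes <- genes[at + seq_len(n_pro)]; at <- at + n_pro
  up_a <- screen_genes[seq_len(n_screen %/% 2)]
  up_b <- setdiff(screen_genes, up_a)
  term_genes <- up_a[seq_len(min(30L, length(up_a)))]

  # --- alignments -----------------------------------------------------
  aln <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    psg <- g %in% psg_genes
    simulate_codon_pair(
      if (psg) len_codons_psg else len_codons_background,
      if (psg) omega_psg else omega_background,
      divergence, seed = derive_seed(seed, paste0("aln", i)),
      gene_id = g)
  })
  names(aln) <- genes

  # --- expression -----------------------------------------------------
  # log-normal baseline abundances give the strong shared expression
  # gradient (hence high sample-sample rank correlations) seen in real
  # transcriptomes
  set.seed(derive_seed(seed, "baseline"))
  baselines <- stats::rnorm(n_genes, mean = 5, sd = 2)
  lib_sizes <- round(stats::runif(2L * n_per_species,
                                  0.7 * library_size,
                                  1.3 * library_size))
  truth <- expression_truth(
    genes,
    baseline_log2 = baselines,
    frac_species = 0, frac_sex = 0, frac_residual = 1,
    species_direction = "none", sd_total = 0.7)
  truth$frac_species[match(screen_genes, genes)] <- frac_screen
  truth$frac_residual[match(screen_genes, genes)] <- 1 - frac_screen
  truth$species_direction[match(up_a, genes)] <- "up_in_A"
  truth$species_direction[match(up_b, genes)] <- "up_in_B"
  # anti list: down in the long-lived species A by 1.0 log2 unit
  # (half-offset 0.5) with residual sd 0.5
  i_anti <- match(anti_genes, genes)
  truth$sd_total[i_anti] <- sqrt(0.5)
  truth$frac_species[i_anti] <- 0.5
  truth$frac_residual[i_anti] <- 0.5
  truth$species_direction[i_anti] <- "up_in_B"
  design <- sample_design(n_per_species, library_size = lib_sizes)
  sim <- simulate_counts(truth, design,
                         seed = derive_seed(seed, "counts"))

  # --- annotation and lists -------------------------------------------
  ann <- simulate_annotation(
    genes, n_terms = n_terms, term_size_range = c(10L, 40L),
    planted_terms = list(T9000 = term_genes),
    seed = derive_seed(seed, "annotation"))

  paths <- list(
    alignments = file.path(dir, "alignments.fasta"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    anti = file.path(dir, "anti_longevity.txt"),
    pro = file.path(dir, "pro_longevity.txt"),
    truth = file.path(dir, "truth.tsv"))
  write_codon_alignments(aln, paths$alignments)
  write_matrix_tsv(sim$counts, paths$counts)
  write_tsv(as.data.frame(design), paths$samples)
  write_tsv(ann, paths$annotation)
  writeLines(anti_genes, paths$anti)
  writeLines(pro_genes, paths$pro)
  truth_out <- truth
  truth_out$is_psg <- truth$gene_id %in% psg_genes
  write_tsv(truth_out, paths$truth)

  invisible(c(paths, list(truth = truth, psg_genes = psg_genes,
                          screen_genes = screen_genes,
                          term_genes = term_genes,
                          anti_genes = anti_genes,
                          pro_genes = pro_genes)))
}
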