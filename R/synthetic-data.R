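# Synthetic ground-truth generators: codon pairs evolved under a
# controllable Ka/Ks ratio, count matrices with species/sex/residual
# variance components, GO-style annotations and longevity gene lists.
#
# Variance-fraction convention: the species and sex contributions are
# fixed half-offsets of magnitude sd_total * sqrt(frac / 2). For a
# balanced 2-level factor this makes the implied random-effect
# variance component (as recovered by balanced ANOVA method of moments
# or REML) equal sd_total^2 * frac, so requested fractions are the
# estimand of the variance-partition module; on zero-residual data the
# ANOVA sum-of-squares decomposition equals the requested
# species:sex ratio exactly.

#' Per-gene expression ground truth
#'
#' Each gene carries a baseline log2 mean, variance fractions for
#' species, sex and residual (summing to 1), a per-gene total latent
#' standard deviation, and a species direction. The species and sex
#' components are realized as fixed half-offsets `+/- sd_total *
#' sqrt(frac / 2)`, scaled so the implied 2-level random-effect
#' variance component equals `sd_total^2 * frac` (the estimand of
#' [fit_gene_lmm]) and the noiseless latent ANOVA decomposition equals
#' the requested species:sex ratio exactly.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param baseline_log2 Baseline log2 expression per gene (recycled).
#' @param frac_species,frac_sex,frac_residual Variance fractions per
#'   gene (recycled); each row must sum to 1.
#' @param species_direction `"up_in_A"`, `"up_in_B"` or `"none"`
#'   (recycled). `"none"` with a positive species fraction gets a
#'   random sign when simulating.
#' @param sd_total Total latent log2 standard deviation per gene
#'   (recycled, default 1).
#'
#' @return A data.frame of class `expression_truth`.
#' @export
expression_truth <- function(gene_ids,
                             baseline_log2 = 5,
                             frac_species = 0,
                             frac_sex = 0,
                             frac_residual = 1,
                             species_direction = "none",
                             sd_total = 1) {
  n <- length(gene_ids)
  stopifnot(n >= 1L, !anyDuplicated(gene_ids))
  truth <- data.frame(gene_id = as.character(gene_ids),
                      baseline_log2 = rep_len(baseline_log2, n),
                      frac_species = rep_len(frac_species, n),
                      frac_sex = rep_len(frac_sex, n),
                      frac_residual = rep_len(frac_residual, n),
                      species_direction = rep_len(species_direction, n),
                      sd_total = rep_len(sd_total, n),
                      stringsAsFactors = FALSE)
  fr <- truth[, c("frac_species", "frac_sex", "frac_residual")]
  if (any(fr < 0) || any(abs(rowSums(fr) - 1) > 1e-8)) {
    stop("variance fractions must be nonnegative and sum to 1")
  }
  if (!all(truth$species_direction %in%
           c("up_in_A", "up_in_B", "none"))) {
    stop("invalid species_direction")
  }
  class(truth) <- c("expression_truth", "data.frame")
  truth
}

#' Two-species, mixed-sex sample design
#'
#' Sex is assigned alternately F/M within species so the crossed
#' random-effects design stays balanced at small n.
#'
#' @param n_per_species Individuals per species (default 8).
#' @param species Two species labels; the first is taken as the
#'   long-lived species throughout the pipeline.
#' @param library_size Expected sequencing depth per sample (recycled).
#'
#' @return A data.frame of class `sample_design` with columns
#'   `sample_id`, `species`, `sex`, `library_size`.
#' @export
sample_design <- function(n_per_species = 8L,
                          species = c("species_A", "species_B"),
                          library_size = 3e6) {
  stopifnot(length(species) == 2L, n_per_species >= 2L)
  n <- 2L * n_per_species
  sp <- rep(species, each = n_per_species)
  sex <- rep(c("F", "M"), length.out = n_per_species)
  out <- data.frame(
    sample_id = paste0(rep(c("A", "B"), each = n_per_species),
                       seq_len(n_per_species)),
    species = sp,
    sex = rep(sex, 2L),
    library_size = rep_len(library_size, n),
    stringsAsFactors = FALSE)
  class(out) <- c("sample_design", "data.frame")
  out
}

#' Simulate a pairwise codon alignment under a target Ka/Ks ratio
#'
#' A stop-free ancestral codon sequence is evolved independently into
#' two descendants. Single-nucleotide changes are proposed uniformly;
#' nonsynonymous proposals are accepted with probability `min(omega,
#' 1)`, synonymous proposals with probability `min(1/omega, 1)`, and
#' proposals creating stop codons are rejected, so the realized
#' nonsynonymous/synonymous rate ratio approximates the requested
#' omega. The number of proposals is set so the expected accepted
#' divergence between the two descendants equals `target_divergence`
#' substitutions per nucleotide site.
#'
#' @param length_codons Number of codons (>= 1).
#' @param omega Target Ka/Ks ratio (>= 0).
#' @param target_divergence Expected substitutions per site between the
#'   two sequences (>= 0).
#' @param seed Integer seed; fixed seed gives identical output.
#' @param gene_id,species_a,species_b Labels for the alignment.
#'
#' @return A [codon_alignment].
#' @export
simulate_codon_pair <- function(length_codons, omega, target_divergence,
                                seed, gene_id = "gene",
                                species_a = "species_A",
                                species_b = "species_B") {
  stopifnot(length_codons >= 1L, omega >= 0, target_divergence >= 0)
  set.seed(seed)
  tb <- .codon_tables()
  nonstop <- which(!tb$is_stop)
  anc <- sample(nonstop, length_codons, replace = TRUE)
  acc_non <- min(omega, 1)
  acc_syn <- min(1 / max(omega, 1e-9), 1)
  desc <- lapply(1:2, function(i) {
    .evolve_codons(anc, target_divergence / 2, acc_syn, acc_non, tb)
  })
  codon_alignment(gene_id,
                  paste(tb$codons[desc[[1]]], collapse = ""),
                  paste(tb$codons[desc[[2]]], collapse = ""),
                  species_a, species_b)
}

# Evolve integer codon indices to an expected `div` accepted
# substitutions per nucleotide site.
.evolve_codons <- function(codons, div, acc_syn, acc_non, tb) {
  L <- length(codons)
  if (div == 0) return(codons)
  # expected acceptance probability of a uniform proposal, per codon
  pacc <- function(ci) {
    ty <- tb$mutant_type[ci, , ]
    (sum(ty == 1L) * acc_syn + sum(ty == 2L) * acc_non) / 9
  }
  mean_acc <- mean(vapply(codons, pacc, numeric(1)))
  if (mean_acc <= 0) return(codons)
  n_prop <- round(3 * L * div / mean_acc)
  if (n_prop == 0L) return(codons)
  hits <- tabulate(sample.int(L, n_prop, replace = TRUE), L)
  # single-proposal codons: fully vectorized
  one <- which(hits == 1L)
  if (length(one) > 0L) {
    pos <- sample.int(3L, length(one), replace = TRUE)
    alt <- sample.int(3L, length(one), replace = TRUE)
    ci <- codons[one]
    mi <- tb$mutant_idx[cbind(ci, pos, alt)]
    ty <- tb$mutant_type[cbind(ci, pos, alt)]
    u <- stats::runif(length(one))
    accept <- (ty == 1L & u < acc_syn) | (ty == 2L & u < acc_non)
    codons[one[accept]] <- mi[accept]
  }
  # multi-proposal codons: sequential within codon
  multi <- which(hits > 1L)
  for (i in multi) {
    for (k in seq_len(hits[i])) {
      pos <- sample.int(3L, 1L)
      alt <- sample.int(3L, 1L)
      mi <- tb$mutant_idx[codons[i], pos, alt]
      ty <- tb$mutant_type[codons[i], pos, alt]
      u <- stats::runif(1L)
      if ((ty == 1L && u < acc_syn) || (ty == 2L && u < acc_non)) {
        codons[i] <- mi
      }
    }
  }
  codons
}

#' Simulate a count matrix from expression ground truth
#'
#' Latent per-sample log2 expression is `baseline + species_component +
#' sex_component + residual`, with the species and sex components fixed
#' half-offsets of magnitude `sd_total * sqrt(frac / 2)` (signed by
#' `species_direction`, random sign for `"none"` and for sex) and
#' residual noise `N(0, sd_total^2 * frac_residual)`. Counts are drawn
#' as Poisson (or negative binomial if `dispersion > 0`) around
#' `library_size * 2^y / sum(2^y)` per sample.
#'
#' @param truth An [expression_truth] table.
#' @param design A [sample_design] table.
#' @param seed Integer seed; fixed seed gives an identical matrix.
#' @param dispersion Negative-binomial dispersion (0 = Poisson).
#'
#' @return List with `counts` (gene x sample integer matrix), `samples`
#'   (the design), and `latent` (the latent log2 matrix).
#' @export
simulate_counts <- function(truth, design, seed, dispersion = 0) {
  stopifnot(inherits(truth, "expression_truth"),
            inherits(design, "sample_design"))
  set.seed(seed)
  G <- nrow(truth)
  n <- nrow(design)
  species <- design$species
  spA <- species[1] # first species listed = species A (long-lived)
  is_a <- species == spA
  sexF <- design$sex == "F"

  sp_sign <- ifelse(truth$species_direction == "up_in_A", 1,
                    ifelse(truth$species_direction == "up_in_B", -1,
                           sample(c(-1, 1), G, replace = TRUE)))
  sex_sign <- sample(c(-1, 1), G, replace = TRUE)
  d_sp <- truth$sd_total * sqrt(truth$frac_species / 2) * sp_sign
  d_sex <- truth$sd_total * sqrt(truth$frac_sex / 2) * sex_sign
  sd_res <- truth$sd_total * sqrt(truth$frac_residual)

  y <- matrix(truth$baseline_log2, G, n)
  y <- y + outer(d_sp, ifelse(is_a, 1, -1))
  y <- y + outer(d_sex, ifelse(sexF, 1, -1))
  y <- y + matrix(stats::rnorm(G * n, sd = rep(sd_res, n)), G, n)

  mu <- sweep(2^y, 2, colSums(2^y), "/")
  mu <- sweep(mu, 2, design$library_size, "*")
  counts <- if (dispersion > 0) {
    matrix(stats::rnbinom(G * n, mu = mu, size = 1 / dispersion), G, n)
  } else {
    matrix(stats::rpois(G * n, lambda = mu), G, n)
  }
  dimnames(counts) <- list(truth$gene_id, design$sample_id)
  dimnames(y) <- dimnames(counts)
  list(counts = counts, samples = design, latent = y)
}

#' Simulate a gene-to-term annotation table
#'
#' Non-planted terms receive uniform random gene subsets with sizes
#' drawn uniformly from `term_size_range`; planted terms get exactly
#' their stated member genes.
#'
#' @param genes Character vector of gene identifiers.
#' @param n_terms Number of random (non-planted) terms.
#' @param term_size_range Integer pair `(min, max)` of random term
#'   sizes.
#' @param planted_terms Named list, term id -> character vector of
#'   member genes (must be a subset of `genes`).
#' @param seed Integer seed.
#'
#' @return A data.frame with columns `gene_id`, `term_id`, `term_name`.
#' @export
simulate_annotation <- function(genes, n_terms,
                                term_size_range = c(10L, 40L),
                                planted_terms = list(), seed = 1L) {
  set.seed(seed)
  stopifnot(n_terms >= 0L, length(term_size_range) == 2L,
            term_size_range[1] <= term_size_range[2])
  if (term_size_range[2] > length(genes) && n_terms > 0L) {
    stop("term size range exceeds number of genes")
  }
  if (length(planted_terms) > 0L &&
      !all(unlist(planted_terms) %in% genes)) {
    stop("planted member genes must be a subset of genes")
  }
  rows <- list()
  if (n_terms > 0L) {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                    n_terms, replace = TRUE)
    for (i in seq_len(n_terms)) {
      tid <- sprintf("T%04d", i)
      rows[[tid]] <- data.frame(gene_id = sample(genes, sizes[i]),
                                term_id = tid,
                                term_name = paste("random process", i),
                                stringsAsFactors = FALSE)
    }
  }
  for (tid in names(planted_terms)) {
    rows[[tid]] <- data.frame(gene_id = planted_terms[[tid]],
                              term_id = tid,
                              term_name = paste("planted process", tid),
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), term_id = character(0),
                      term_name = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$term_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
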