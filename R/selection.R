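# Pairwise Ka/Ks estimation by Nei-Gojobori (1986) counting with
# Jukes-Cantor correction, Fisher exact positive-selection test,
# alignment filters, and multi-species all-pairs scans.

#' Pairwise codon alignment for one gene
#'
#' @param gene_id Gene identifier.
#' @param seq_a,seq_b Aligned coding sequences (equal length, divisible
#'   by 3, alphabet `A/C/G/T/-`); lower case is accepted and folded.
#' @param species_a,species_b Species labels.
#'
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(gene_id, seq_a, seq_b,
                            species_a = "species_A",
                            species_b = "species_B") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length")
  }
  if (nchar(seq_a) %% 3 != 0) {
    stop("alignment length must be divisible by 3")
  }
  if (grepl("[^ACGT-]", seq_a) || grepl("[^ACGT-]", seq_b)) {
    stop("alignment alphabet must be A/C/G/T/-")
  }
  structure(list(gene_id = gene_id, seq_a = seq_a, seq_b = seq_b,
                 species_a = species_a, species_b = species_b),
            class = "codon_alignment")
}

#' NG86 synonymous/nonsynonymous site counts of a codon
#'
#' For each of the three positions, the fraction of the three
#' single-nucleotide mutants that are synonymous is added to S; mutants
#' creating stop codons count as nonsynonymous. `N = 3 - S`.
#'
#' @param codon A stop-free 3-mer over `A/C/G/T`.
#'
#' @return List with elements `S` and `N`.
#' @export
ng86_sites <- function(codon) {
  tb <- .codon_tables()
  codon <- toupper(codon)
  ci <- tb$idx[[codon]]
  if (is.null(ci)) stop("ambiguous or invalid codon: ", codon)
  if (tb$is_stop[ci]) stop("stop codon: ", codon)
  s <- tb$syn_sites[ci]
  list(S = s, N = 3 - s)
}

#' NG86 substitution counts between two codons
#'
#' Synonymous/nonsynonymous step counts averaged over all orderings of
#' the differing positions. Mutational paths passing through a stop
#' codon are excluded; if every path is blocked, all paths are included.
#' `Sd + Nd` equals the number of differing positions.
#'
#' @param codon_a,codon_b Stop-free 3-mers over `A/C/G/T`.
#'
#' @return List with elements `Sd` and `Nd`.
#' @export
ng86_substitutions <- function(codon_a, codon_b) {
  tb <- .pair_tables()
  ai <- tb$idx[[toupper(codon_a)]]
  bi <- tb$idx[[toupper(codon_b)]]
  if (is.null(ai) || is.null(bi)) stop("ambiguous or invalid codon")
  if (tb$is_stop[ai] || tb$is_stop[bi]) stop("stop codon")
  list(Sd = tb$sd_mat[ai, bi], Nd = tb$nd_mat[ai, bi])
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) log(1 - (4/3) p)`; undefined (`NA`) at saturation
#' (`p >= 3/4`).
#'
#' @param p Observed proportion of substituted sites.
#'
#' @return Corrected distance, or `NA` if saturated.
#' @export
jukes_cantor <- function(p) {
  # + 0 normalizes the signed zero at p = 0
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3) + 0)
}

#' Ka/Ks estimate for one pairwise codon alignment
#'
#' Codons containing gaps, ambiguity or a stop in either sequence are
#' excluded. Sites are counted per sequence (NG86) and averaged;
#' substitutions are pathway-averaged and summed. Proportions are
#' Jukes-Cantor corrected to give Ka and Ks, and a one-sided Fisher
#' exact test on the rounded 2x2 substitution/site table scores
#' positive selection (excess of nonsynonymous substitution).
#'
#' @param alignment A [codon_alignment].
#'
#' @return List of class `kaks_result` with counts (`S`, `N`, `Sd`,
#'   `Nd`), rates (`Ka`, `Ks`, `omega`), the Fisher `p_value`, the
#'   purifying-tail `p_purifying`, compared/total lengths and
#'   `filter_flags` (character vector; may include `saturated`,
#'   `undefined_ratio`).
#' @export
kaks_pair <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  tb <- .pair_tables()
  len <- nchar(alignment$seq_a)
  starts <- seq(1, len, by = 3)
  ca <- substring(alignment$seq_a, starts, starts + 2)
  cb <- substring(alignment$seq_b, starts, starts + 2)
  ia <- match(ca, tb$codons) # NA for codons containing gaps
  ib <- match(cb, tb$codons)
  ok <- !is.na(ia) & !is.na(ib) & !tb$is_stop[ifelse(is.na(ia), 1, ia)] &
    !tb$is_stop[ifelse(is.na(ib), 1, ib)]
  ncmp <- sum(ok)
  if (ncmp == 0L) stop("no comparable codons in alignment ",
                       alignment$gene_id)
  ia <- ia[ok]; ib <- ib[ok]
  S <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  N <- 3 * ncmp - S
  Sd <- sum(tb$sd_mat[cbind(ia, ib)])
  Nd <- sum(tb$nd_mat[cbind(ia, ib)])
  ps <- Sd / S
  pn <- Nd / N
  Ks <- jukes_cantor(ps)
  Ka <- jukes_cantor(pn)
  flags <- character(0)
  if (is.na(Ka) || is.na(Ks)) flags <- c(flags, "saturated")
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  if (is.na(omega)) flags <- c(flags, "undefined_ratio")
  fish_tab <- rbind(c(round(Nd), round(N - Nd)),
                    c(round(Sd), round(S - Sd)))
  p <- fisher_exact_2x2(fish_tab, "greater")$p_value
  p_pur <- fisher_exact_2x2(fish_tab, "less")$p_value
  structure(list(gene_id = alignment$gene_id,
                 S = S, N = N, Sd = Sd, Nd = Nd,
                 Ka = Ka, Ks = Ks, omega = omega,
                 p_value = p, p_purifying = p_pur,
                 compared_bp = 3L * ncmp, total_columns = len,
                 filter_flags = flags),
            class = "kaks_result")
}

#' Genome-wide positive-selection scan over pairwise alignments
#'
#' Runs [kaks_pair] per gene, applies the short-alignment and
#' low-coverage filters, BH-adjusts the Fisher p-values across genes
#' and classifies each gene. A gene is `positive` iff `omega > 1`, its
#' FDR is below `kaks_fdr` and it carries no filter flag; `purifying`
#' iff `omega < 1` with purifying-tail FDR below `kaks_fdr`.
#'
#' @param alignments List of [codon_alignment] objects.
#' @param kaks_fdr FDR threshold for calling selection (default 0.05).
#' @param min_len_bp Minimum compared alignment length in bp (default
#'   100); shorter genes are flagged `short_alignment`.
#' @param min_coverage Minimum ratio of compared length to total
#'   alignment columns (default 0.8); lower is flagged `low_coverage`.
#'
#' @return A data.frame, one row per gene, sorted by `gene_id`:
#'   counts, rates, `p`, `fdr`, `p_pur`, `fdr_pur`, `classification`,
#'   comma-separated `flags`.
#' @export
selection_scan <- function(alignments, kaks_fdr = 0.05,
                           min_len_bp = 100L, min_coverage = 0.8) {
  stopifnot(length(alignments) >= 1L)
  rows <- lapply(alignments, function(al) {
    res <- kaks_pair(al)
    flags <- res$filter_flags
    if (res$compared_bp < min_len_bp) {
      flags <- c(flags, "short_alignment")
    }
    if (res$compared_bp / res$total_columns < min_coverage) {
      flags <- c(flags, "low_coverage")
    }
    data.frame(gene_id = res$gene_id, Sd = res$Sd, Nd = res$Nd,
               S = res$S, N = res$N, Ka = res$Ka, Ks = res$Ks,
               omega = res$omega, p = res$p_value,
               p_pur = res$p_purifying,
               compared_bp = res$compared_bp,
               total_columns = res$total_columns,
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out$fdr <- bh_adjust(out$p)
  out$fdr_pur <- bh_adjust(out$p_pur)
  flagged <- nzchar(out$flags)
  out$classification <- "none"
  out$classification[!is.na(out$omega) & out$omega < 1 &
                       !is.na(out$fdr_pur) &
                       out$fdr_pur < kaks_fdr] <- "purifying"
  out$classification[!is.na(out$omega) & out$omega > 1 &
                       !is.na(out$fdr) & out$fdr < kaks_fdr &
                       !flagged] <- "positive"
  out
}

#' All-pairs Ka/Ks scan across several species
#'
#' Runs [selection_scan] for each species pair and assembles gene-by-
#' pair matrices of omega and FDR (the layout of a pairwise selection
#' heat map across k species).
#'
#' @param alignments_by_pair Named list (`"spA|spB"`) of lists of
#'   [codon_alignment] objects; a gene missing from a pair is simply
#'   absent from that pair's scan.
#' @param ... Passed to [selection_scan].
#'
#' @return List with `scans` (per-pair data.frames), `psg` (per-pair
#'   character vectors of positively selected genes), and `omega` /
#'   `fdr` matrices (genes x pairs, `NA` where a gene is missing).
#' @export
pairwise_species_scan <- function(alignments_by_pair, ...) {
  stopifnot(length(alignments_by_pair) >= 1L,
            !is.null(names(alignments_by_pair)))
  scans <- lapply(alignments_by_pair, selection_scan, ...)
  genes <- sort(unique(unlist(lapply(scans, `[[`, "gene_id"))))
  pairs <- names(scans)
  omega <- fdr <- matrix(NA_real_, length(genes), length(pairs),
                         dimnames = list(genes, pairs))
  for (pr in pairs) {
    sc <- scans[[pr]]
    omega[sc$gene_id, pr] <- sc$omega
    fdr[sc$gene_id, pr] <- sc$fdr
  }
  psg <- lapply(scans, function(sc) {
    sc$gene_id[sc$classification == "positive"]
  })
  list(scans = scans, psg = psg, omega = omega, fdr = fdr)
}

#' Read pairwise codon alignments from a multi-record FASTA file
#'
#' Records are headed `geneID|species`; each gene must have exactly two
#' records.
#'
#' @param path FASTA file path.
#'
#' @return Named list of [codon_alignment] objects.
#' @export
read_codon_alignments <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  genes <- vapply(parts, `[`, character(1), 1L)
  species <- vapply(parts, `[`, character(1), 2L)
  out <- list()
  for (g in unique(genes)) {
    i <- which(genes == g)
    if (length(i) != 2L) {
      stop("gene ", g, " must have exactly 2 records, found ",
           length(i))
    }
    out[[g]] <- codon_alignment(g, as.character(seqs[[i[1]]]),
                                as.character(seqs[[i[2]]]),
                                species[i[1]], species[i[2]])
  }
  out[order(names(out))]
}

#' Write pairwise codon alignments to one multi-record FASTA file
#'
#' @param alignments List of [codon_alignment] objects.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_codon_alignments <- function(alignments, path) {
  recs <- unlist(unname(lapply(alignments, function(al) {
    stats::setNames(c(al$seq_a, al$seq_b),
                    paste(al$gene_id, c(al$species_a, al$species_b),
                          sep = "|"))
  })))
  Biostrings::writeXStringSet(Biostrings::BStringSet(recs), path)
  invisible(path)
}
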