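# Anti-/pro-longevity signature tests: a paired one-tailed signed-rank
# test of list-gene expression between the long- and short-lived
# species, judged against a gene-subsampling null distribution
# summarized by its 95% highest density interval.

#' Paired signed-rank test of a gene list's species expression
#'
#' Tests the per-gene paired differences (mean in species A, the
#' long-lived species, minus mean in species B) over the list genes.
#' `alternative = "less"` tests for lower expression in the long-lived
#' species (the expectation for anti-longevity genes). List genes
#' absent from the expression table are dropped with a message.
#'
#' @param means Output of [species_gene_means].
#' @param gene_list Character vector of gene ids.
#' @param alternative Test direction (default `"less"`).
#'
#' @return A [test_result] with attribute `n_genes` (genes used).
#' @export
signature_test <- function(means, gene_list,
                           alternative = c("less", "greater",
                                           "two_sided")) {
  alternative <- .match_alt(match.arg(alternative))
  gene_list <- unique(as.character(gene_list))
  hit <- gene_list %in% means$gene_id
  if (any(!hit)) {
    message(sum(!hit), " list gene(s) missing from expression table; ",
            "dropped")
  }
  genes <- gene_list[hit]
  if (length(genes) < 2L) {
    stop("fewer than 2 list genes present in the expression table")
  }
  i <- match(genes, means$gene_id)
  d <- means$mean_a[i] - means$mean_b[i]
  res <- wilcoxon_signed_rank(d, alternative)
  attr(res, "n_genes") <- length(genes)
  res
}

#' Subsampling null distribution for the signature test
#'
#' Repeatedly draws `list_size` genes uniformly without replacement
#' from the background, runs [signature_test] on each draw and collects
#' the p-values; the stated-mass HDI of the collected p-values is
#' attached as the null acceptance region.
#'
#' @param means Output of [species_gene_means].
#' @param background Character vector of background gene ids (must all
#'   be present in `means` and have at least `list_size` members).
#' @param list_size Genes per draw (the tested list's usable size).
#' @param B Number of draws (default 1000).
#' @param seed Integer seed fixing the full draw sequence.
#' @param alternative Test direction (default `"less"`).
#' @param hdi_mass HDI mass (default 0.95).
#'
#' @return List of class `null_distribution`: `p_values` (length `B`),
#'   `B`, `list_size`, `seed`, `hdi` (an `interval`).
#' @export
subsample_null <- function(means, background, list_size, B = 1000L,
                           seed = 1L, alternative = "less",
                           hdi_mass = 0.95) {
  background <- unique(as.character(background))
  background <- background[background %in% means$gene_id]
  if (length(background) < list_size) {
    stop("background smaller than list_size")
  }
  stopifnot(B >= 1L)
  set.seed(seed)
  i <- match(background, means$gene_id)
  diffs <- means$mean_a[i] - means$mean_b[i]
  p <- vapply(seq_len(B), function(b) {
    d <- diffs[sample.int(length(diffs), list_size)]
    wilcoxon_signed_rank(d, alternative)$p_value
  }, numeric(1))
  structure(list(p_values = p, B = B, list_size = list_size,
                 seed = seed, alternative = alternative,
                 hdi = hdi(p, hdi_mass)),
            class = "null_distribution")
}

#' Significance call against the subsampling null
#'
#' The observed p-value is significant iff it falls strictly outside
#' the null HDI.
#'
#' @param observed A [test_result] from [signature_test].
#' @param null A [subsample_null] result.
#'
#' @return List of class `signature_decision`: `observed_p`,
#'   `inside_hdi`, `call` (`"significant"` / `"not_significant"`).
#' @export
signature_call <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  p <- observed$p_value
  outside <- p < null$hdi$lower || p > null$hdi$upper
  structure(list(observed_p = p, inside_hdi = !outside,
                 hdi = null$hdi,
                 call = if (outside) "significant"
                        else "not_significant"),
            class = "signature_decision")
}

#' @export
print.signature_decision <- function(x, ...) {
  cat(sprintf("observed p = %g vs null %.0f%% HDI [%g, %g]: %s\n",
              x$observed_p, 100 * x$hdi$mass, x$hdi$lower,
              x$hdi$upper, x$call))
  invisible(x)
}
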