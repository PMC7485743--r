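# GO-style term analysis: hypergeometric over-representation of the
# direction-specific screened gene sets, top-term selection, and
# term-level paired one-tailed signed-rank tests of species expression.

# Upper-tail hypergeometric probability P(X >= k) of drawing k or more
# term genes when sampling n genes from a background of size nn
# containing kk term genes. Exact tail sum.
.hyper_upper <- function(k, kk, nn, n) {
  hi <- min(kk, n)
  if (k > hi) return(0)
  xs <- max(k, max(0, n - (nn - kk))):hi
  sum(exp(lchoose(kk, xs) + lchoose(nn - kk, n - xs) - lchoose(nn, n)))
}

#' Hypergeometric over-representation test
#'
#' For each annotation term, an upper-tail hypergeometric test of the
#' overlap between the foreground set and the term's genes within the
#' background, BH-adjusted across the tested terms. Terms overlapping
#' the foreground by fewer than `min_overlap` genes are not tested.
#'
#' @param foreground Character vector of genes (subset of background).
#' @param background Character vector of universe genes.
#' @param annotation data.frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`.
#' @param fdr_threshold Enrichment FDR threshold (default 0.05).
#' @param min_overlap Minimum foreground overlap to test (default 3).
#'
#' @return data.frame with one row per term present in the background:
#'   `term_id`, `term_name`, `n_term_background`, `n_term_foreground`,
#'   `p` / `fdr` (`NA` for untested terms), `enriched`.
#' @export
hypergeom_enrich <- function(foreground, background, annotation,
                             fdr_threshold = 0.05, min_overlap = 3L) {
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of background")
  }
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  if (is.null(ann$term_name)) ann$term_name <- ann$term_id
  if (nrow(ann) == 0L) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      n_term_background = integer(0),
                      n_term_foreground = integer(0),
                      p = numeric(0), fdr = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE))
  }
  terms <- split(ann$gene_id, ann$term_id)
  names_tab <- ann$term_name[match(names(terms), ann$term_id)]
  nn <- length(background)
  n <- length(foreground)
  k_bg <- vapply(terms, length, integer(1))
  k_fg <- vapply(terms, function(g) sum(g %in% foreground), integer(1))
  tested <- k_fg >= min_overlap
  p <- rep(NA_real_, length(terms))
  p[tested] <- mapply(function(k, kk) .hyper_upper(k, kk, nn, n),
                      k_fg[tested], k_bg[tested])
  out <- data.frame(term_id = names(terms), term_name = names_tab,
                    n_term_background = k_bg, n_term_foreground = k_fg,
                    p = p, stringsAsFactors = FALSE)
  out <- out[order(out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out$fdr <- bh_adjust(out$p)
  out$enriched <- !is.na(out$fdr) & out$fdr < fdr_threshold &
    out$n_term_foreground >= min_overlap
  out
}

#' Top enriched terms across the two direction-specific runs
#'
#' Union of enriched terms from the up-in-A and up-in-B enrichment
#' runs, de-duplicated (keeping each term's best FDR), ranked by FDR
#' and truncated to `k`.
#'
#' @param enrich_up_a,enrich_up_b Outputs of [hypergeom_enrich].
#' @param k Maximum number of terms returned (default 20).
#'
#' @return data.frame `term_id`, `term_name`, `best_fdr`, FDR-sorted.
#' @export
select_top_terms <- function(enrich_up_a, enrich_up_b, k = 20L) {
  both <- rbind(enrich_up_a[enrich_up_a$enriched, , drop = FALSE],
                enrich_up_b[enrich_up_b$enriched, , drop = FALSE])
  if (nrow(both) == 0L) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      best_fdr = numeric(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(fdr ~ term_id + term_name, data = both,
                          FUN = min)
  names(agg)[names(agg) == "fdr"] <- "best_fdr"
  agg <- agg[order(agg$best_fdr, agg$term_id), , drop = FALSE]
  rownames(agg) <- NULL
  utils::head(agg, k)
}

#' Term-level paired differential expression
#'
#' For each term, the paired vector of per-gene species means (species
#' A vs species B) over the term's member genes is tested with
#' one-tailed Wilcoxon signed-rank tests in both directions;
#' BH adjustment is applied per direction across terms and the
#' significant direction (if any) is called.
#'
#' @param means Output of [species_gene_means].
#' @param terms Character vector of term ids to test.
#' @param annotation Annotation data.frame (`gene_id`, `term_id`).
#' @param fdr_threshold Call threshold (default 0.05).
#'
#' @return data.frame with `term_id`, `n_genes`, `p_up_in_A`,
#'   `p_up_in_B`, `fdr_up_in_A`, `fdr_up_in_B`, `call`.
#' @export
term_expression_test <- function(means, terms, annotation,
                                 fdr_threshold = 0.05) {
  terms <- sort(unique(as.character(terms)))
  rows <- lapply(terms, function(tid) {
    genes <- annotation$gene_id[annotation$term_id == tid]
    d <- means$mean_a[match(genes, means$gene_id)] -
      means$mean_b[match(genes, means$gene_id)]
    d <- d[!is.na(d)]
    if (length(d) < 2L) {
      warning("term ", tid, " has fewer than 2 usable genes; skipped")
      return(NULL)
    }
    if (all(d == 0)) {
      # degenerate paired sample: no direction can be called
      return(data.frame(term_id = tid, n_genes = length(d),
                        p_up_in_A = NA_real_, p_up_in_B = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(term_id = tid, n_genes = length(d),
               p_up_in_A = wilcoxon_signed_rank(d, "greater")$p_value,
               p_up_in_B = wilcoxon_signed_rank(d, "less")$p_value,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term_id = character(0), n_genes = integer(0),
                      p_up_in_A = numeric(0), p_up_in_B = numeric(0),
                      fdr_up_in_A = numeric(0), fdr_up_in_B = numeric(0),
                      call = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr_up_in_A <- bh_adjust(out$p_up_in_A)
  out$fdr_up_in_B <- bh_adjust(out$p_up_in_B)
  sig_a <- !is.na(out$fdr_up_in_A) & out$fdr_up_in_A < fdr_threshold
  sig_b <- !is.na(out$fdr_up_in_B) & out$fdr_up_in_B < fdr_threshold
  out$call <- ifelse(sig_a & !sig_b, "higher_in_A",
                     ifelse(sig_b & !sig_a, "higher_in_B", "none"))
  if (any(sig_a & sig_b)) {
    warning("term significant in both directions; called none")
  }
  out
}
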