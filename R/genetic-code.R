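# Codon lookup tables (universal genetic code), built lazily from
# Biostrings::GENETIC_CODE and cached in the package environment.

.codon_env <- new.env(parent = emptyenv())

.codon_tables <- function() {
  if (!is.null(.codon_env$codons)) return(.codon_env)
  nts <- c("A", "C", "G", "T")
  grid <- expand.grid(p3 = nts, p2 = nts, p1 = nts,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$p1, grid$p2, grid$p3)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  is_stop <- aa == "*"
  idx <- stats::setNames(seq_along(codons), codons)

  # mutant_idx[c, p, j]: codon index after substituting alternative j
  # (of the 3 non-identical nucleotides, in ACGT order) at position p.
  # mutant_type: 0 = creates stop, 1 = synonymous, 2 = nonsynonymous.
  mutant_idx <- array(0L, dim = c(64, 3, 3))
  mutant_type <- array(0L, dim = c(64, 3, 3))
  for (ci in seq_along(codons)) {
    base <- strsplit(codons[ci], "")[[1]]
    for (p in 1:3) {
      alts <- nts[nts != base[p]]
      for (j in 1:3) {
        mut <- base
        mut[p] <- alts[j]
        mi <- idx[[paste0(mut, collapse = "")]]
        mutant_idx[ci, p, j] <- mi
        mutant_type[ci, p, j] <-
          if (is_stop[mi]) 0L else if (aa[mi] == aa[ci]) 1L else 2L
      }
    }
  }

  # NG86 synonymous site count per codon: per position, the fraction of
  # the 3 single-nucleotide mutants that are synonymous (stop-creating
  # mutants count as nonsynonymous).
  syn_sites <- vapply(seq_along(codons), function(ci) {
    sum(mutant_type[ci, , ] == 1L) / 3
  }, numeric(1))
  syn_sites[is_stop] <- NA_real_

  .codon_env$codons <- codons
  .codon_env$aa <- aa
  .codon_env$is_stop <- is_stop
  .codon_env$idx <- idx
  .codon_env$mutant_idx <- mutant_idx
  .codon_env$mutant_type <- mutant_type
  .codon_env$syn_sites <- syn_sites
  .codon_env
}

# Pathway-averaged substitution counts for every ordered codon pair,
# cached as 64x64 matrices (sd = synonymous, nd = nonsynonymous steps).
.pair_tables <- function() {
  tb <- .codon_tables()
  if (!is.null(.codon_env$sd_mat)) return(.codon_env)
  sd_mat <- matrix(NA_real_, 64, 64)
  nd_mat <- matrix(NA_real_, 64, 64)
  nonstop <- which(!tb$is_stop)
  split_nt <- strsplit(tb$codons, "")
  for (ai in nonstop) {
    for (bi in nonstop) {
      cnt <- .path_counts(split_nt[[ai]], split_nt[[bi]], tb)
      sd_mat[ai, bi] <- cnt[1]
      nd_mat[ai, bi] <- cnt[2]
    }
  }
  .codon_env$sd_mat <- sd_mat
  .codon_env$nd_mat <- nd_mat
  .codon_env
}

# Average (syn, nonsyn) step counts over all orderings of the differing
# positions; paths through a stop codon are excluded unless every path
# is blocked, in which case all paths are included.
.path_counts <- function(a, b, tb) {
  diffs <- which(a != b)
  nd <- length(diffs)
  if (nd == 0L) return(c(0, 0))
  perms <- switch(nd,
                  list(diffs),
                  list(diffs, rev(diffs)),
                  {
                    p <- list()
                    for (i in 1:3) for (j in 1:3) {
                      if (i != j) {
                        k <- setdiff(1:3, c(i, j))
                        p[[length(p) + 1L]] <-
                          c(diffs[i], diffs[j], diffs[k])
                      }
                    }
                    p
                  })
  step_counts <- matrix(NA_real_, length(perms), 2)
  blocked <- logical(length(perms))
  for (pi in seq_along(perms)) {
    cur <- a
    syn <- 0; non <- 0
    for (pos in perms[[pi]]) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa_cur <- tb$aa[tb$idx[[paste0(cur, collapse = "")]]]
      aa_nxt <- tb$aa[tb$idx[[paste0(nxt, collapse = "")]]]
      if (aa_nxt == "*" && !identical(nxt, b)) blocked[pi] <- TRUE
      if (aa_cur == aa_nxt && aa_cur != "*") syn <- syn + 1
      else non <- non + 1
      cur <- nxt
    }
    step_counts[pi, ] <- c(syn, non)
  }
  use <- if (all(blocked)) rep(TRUE, length(perms)) else !blocked
  colMeans(step_counts[use, , drop = FALSE])
}
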