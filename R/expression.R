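# Count-matrix handling: expression filtering, TMM normalization,
# log2-CPM transformation, correlation structure, rank-based
# differential expression, and the selection-vs-expression association
# tests.

#' Expression study container
#'
#' Bundles a gene-by-sample count matrix with its sample metadata.
#' Library sizes default to column sums and are recomputed whenever the
#' matrix is filtered.
#'
#' @param counts Nonnegative gene x sample matrix with row and column
#'   names.
#' @param samples data.frame with columns `sample_id`, `species`,
#'   `sex`; row order is matched to the matrix columns. The first
#'   species encountered is taken as species A (the long-lived one).
#'
#' @return An object of class `expression_study` with fields `counts`,
#'   `samples`, `lib_size`, and (after [normalize_log]) `tmm_factor`
#'   and `normalized`.
#' @export
expression_study <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene row names and sample column names")
  }
  if (any(counts < 0)) stop("negative counts")
  req <- c("sample_id", "species", "sex")
  if (!all(req %in% names(samples))) {
    stop("samples must have columns sample_id, species, sex")
  }
  if (!setequal(samples$sample_id, colnames(counts))) {
    stop("sample ids in metadata and count matrix differ")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  sp <- unique(samples$species)
  if (length(sp) != 2L) stop("exactly two species required")
  if (min(table(samples$species)) < 2L) {
    stop("at least 2 samples per species required")
  }
  structure(list(counts = counts, samples = samples,
                 species_a = sp[1], species_b = sp[2],
                 lib_size = colSums(counts),
                 tmm_factor = NULL, normalized = NULL),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples (", x$species_a, "vs", x$species_b,
      ")\n")
  if (!is.null(x$normalized)) cat("  normalized (TMM + log2 CPM)\n")
  invisible(x)
}

#' Drop genes expressed in neither species
#'
#' Under the default `"and"` rule a gene is removed iff its count sum
#' is zero within species A and zero within species B (i.e. expressed
#' in neither). The `"or"` rule removes genes silent in at least one
#' species. Library sizes are recomputed from the filtered matrix;
#' any previous normalization is invalidated.
#'
#' @param study An [expression_study].
#' @param rule `"and"` (default) or `"or"`.
#'
#' @return The filtered [expression_study].
#' @export
filter_unexpressed <- function(study, rule = c("and", "or")) {
  stopifnot(inherits(study, "expression_study"))
  rule <- match.arg(rule)
  a <- study$samples$species == study$species_a
  sum_a <- rowSums(study$counts[, a, drop = FALSE])
  sum_b <- rowSums(study$counts[, !a, drop = FALSE])
  drop <- if (rule == "and") sum_a == 0 & sum_b == 0
          else sum_a == 0 | sum_b == 0
  expression_study(study$counts[!drop, , drop = FALSE], study$samples)
}

# TMM factor of one sample against the reference column
# (trimmed weighted mean of M-values; Robinson & Oshlack 2010).
.tmm_one <- function(obs, ref, n_obs, n_ref,
                     logratio_trim = 0.3, sum_trim = 0.05,
                     do_weighting = TRUE) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- if (do_weighting) {
    sum(logR[keep] / v[keep], na.rm = TRUE) /
      sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values. The reference is the sample whose
#' 75th-percentile count fraction is closest to the mean across
#' samples. Per sample, M (log2 ratio) and A (mean log2 abundance) are
#' computed over genes nonzero in both columns after library-size
#' scaling; M is trimmed 30% from each tail and A 5% from each tail,
#' and the factor is 2 to the weighted mean of the surviving M-values
#' with inverse asymptotic (binomial) variance weights. Factors are
#' rescaled so their log-mean is zero.
#'
#' With precision weighting (the default, matching the reference TMM
#' estimator) factors are only approximately invariant to rescaling a
#' single sample's counts, because the asymptotic binomial weights
#' depend on absolute depth; `do_weighting = FALSE` gives the plain
#' trimmed mean, which is exactly scale-invariant.
#'
#' @param counts Gene x sample matrix (at least 2 samples, each with a
#'   nonzero gene).
#' @param lib_size Library sizes (default: column sums).
#' @param do_weighting Use inverse-variance weights (default `TRUE`).
#'
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, lib_size = colSums(counts),
                        do_weighting = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib_size
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_one(counts[, j], counts[, ref], lib_size[j], lib_size[ref],
             do_weighting = do_weighting)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' TMM-normalized log2 expression
#'
#' `log2(count / (lib_size * tmm_factor) * 1e6 + pseudocount)`; with
#' the default pseudocount of 1 a zero count maps to 0.
#'
#' @param study An [expression_study].
#' @param pseudocount Added inside the log (default 1).
#'
#' @return The study with `tmm_factor` and `normalized` filled in.
#' @export
normalize_log <- function(study, pseudocount = 1) {
  stopifnot(inherits(study, "expression_study"))
  f <- tmm_factors(study$counts, study$lib_size)
  eff <- study$lib_size * f
  study$tmm_factor <- f
  study$normalized <- log2(sweep(study$counts, 2, eff, "/") * 1e6 +
                             pseudocount)
  study
}

#' Sample-sample Spearman correlation structure
#'
#' Full sample x sample Spearman matrix on normalized expression;
#' off-diagonal coefficients are split into intraspecific and
#' interspecific sets, whose medians are reported and compared with a
#' rank-sum test (the sets are unpaired and of unequal size).
#'
#' @param study A normalized [expression_study].
#' @param alternative Alternative for the intra-vs-inter rank-sum test
#'   (default `"greater"`: intraspecific coefficients larger).
#'
#' @return List with `matrix`, `intra`, `inter`, `median_intra`,
#'   `median_inter`, and `test` (a [test_result]).
#' @export
correlation_analysis <- function(study, alternative = "greater") {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(study$normalized)) stop("run normalize_log() first")
  x <- study$normalized
  n <- ncol(x)
  rho <- diag(1, n)
  dimnames(rho) <- list(colnames(x), colnames(x))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rho[i, j] <- rho[j, i] <- spearman_rho(x[, i], x[, j])
    }
  }
  sp <- study$samples$species
  same <- outer(sp, sp, "==")
  ut <- upper.tri(rho)
  intra <- rho[ut & same]
  inter <- rho[ut & !same]
  list(matrix = rho, intra = intra, inter = inter,
       median_intra = stats::median(intra),
       median_inter = stats::median(inter),
       test = wilcoxon_rank_sum(intra, inter, alternative))
}

#' Rank-based differential expression between the two species
#'
#' Per gene, a two-sided Wilcoxon rank-sum test on normalized log2
#' expression between species, BH-adjusted across genes. Log2 fold
#' change is species A mean minus species B mean.
#'
#' @param study A normalized [expression_study].
#' @param fdr_threshold DEG FDR threshold (default 0.05).
#'
#' @return data.frame with `gene_id`, `log2fc`, `p`, `fdr`, `is_DEG`,
#'   sorted by `gene_id`.
#' @export
differential_expression <- function(study, fdr_threshold = 0.05) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(study$normalized)) stop("run normalize_log() first")
  x <- study$normalized
  a <- study$samples$species == study$species_a
  if (sum(a) < 2L || sum(!a) < 2L) {
    stop("at least 2 samples per species required")
  }
  if (nrow(x) == 0L) {
    return(data.frame(gene_id = character(0), log2fc = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      is_DEG = logical(0)))
  }
  p <- vapply(seq_len(nrow(x)), function(g) {
    wilcoxon_rank_sum(x[g, a], x[g, !a], "two_sided")$p_value
  }, numeric(1))
  out <- data.frame(
    gene_id = rownames(x),
    log2fc = rowMeans(x[, a, drop = FALSE]) -
      rowMeans(x[, !a, drop = FALSE]),
    p = p, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out$fdr <- bh_adjust(out$p)
  out$is_DEG <- out$fdr < fdr_threshold
  out
}

#' Association between selection and differential expression
#'
#' Two tests on the genes shared between a DE table and a Ka/Ks scan:
#' a Kolmogorov-Smirnov test comparing the omega distributions of DEGs
#' versus non-DEGs, and a chi-square test of the 2x2 DEG-by-PSG table.
#'
#' @param de Output of [differential_expression].
#' @param kaks Output of [selection_scan].
#'
#' @return List with `ks` and `chi2` [test_result]s and the 2x2
#'   `table`.
#' @export
selection_expression_association <- function(de, kaks) {
  m <- merge(de[, c("gene_id", "is_DEG")],
             kaks[, c("gene_id", "omega", "classification")],
             by = "gene_id")
  if (nrow(m) == 0L) stop("no shared gene ids")
  om_deg <- m$omega[m$is_DEG & !is.na(m$omega)]
  om_non <- m$omega[!m$is_DEG & !is.na(m$omega)]
  if (length(om_deg) == 0L || length(om_non) == 0L) {
    stop("empty stratum: need both DEG and non-DEG genes with omega")
  }
  ks <- ks_2samp(om_deg, om_non)
  psg <- m$classification == "positive"
  tab <- table(factor(m$is_DEG, c(TRUE, FALSE)),
               factor(psg, c(TRUE, FALSE)),
               dnn = c("DEG", "PSG"))
  chi <- chi2_2x2(tab)
  list(ks = ks, chi2 = chi, table = tab)
}

#' Per-gene mean normalized expression by species
#'
#' The paired per-gene summary fed to the GO-term-level and
#' longevity-signature signed-rank tests.
#'
#' @param study A normalized [expression_study].
#'
#' @return data.frame with `gene_id`, `mean_a` (species A, long-lived),
#'   `mean_b`, sorted by `gene_id`.
#' @export
species_gene_means <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(study$normalized)) stop("run normalize_log() first")
  a <- study$samples$species == study$species_a
  out <- data.frame(
    gene_id = rownames(study$normalized),
    mean_a = rowMeans(study$normalized[, a, drop = FALSE]),
    mean_b = rowMeans(study$normalized[, !a, drop = FALSE]),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
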