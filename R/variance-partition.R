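# Per-gene crossed random-effects variance decomposition: species and
# sex modelled as zero-mean random effects, everything else residual.
# Components are estimated by REML on the profiled criterion, with
# nonnegativity enforced by box constraints on the variance ratios.

# -2 * REML log-likelihood (profiled over the residual variance) as a
# function of variance ratios gamma = sigma_k^2 / sigma_e^2.
.reml_crit <- function(gamma, y, za, zb) {
  n <- length(y)
  v <- diag(n) + gamma[1] * tcrossprod(za) + gamma[2] * tcrossprod(zb)
  ch <- tryCatch(chol(v), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet_v <- 2 * sum(log(diag(ch)))
  vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  xtvx <- sum(vi_1)            # X = 1 column of ones
  beta <- sum(vi_y) / xtvx
  rss <- sum(y * vi_y) - beta * sum(vi_y) # y' P y
  rss <- max(rss, 1e-12 * max(sum(y^2), 1))
  logdet_v + log(xtvx) + (n - 1) * log(rss)
}

# Method-of-moments starting values (balanced two-way ANOVA, truncated
# at zero); returns c(gamma_species, gamma_sex).
.mom_start <- function(y, species, sex) {
  fit <- stats::lm(y ~ species + sex)
  an <- suppressWarnings(stats::anova(fit))
  ms <- an[["Mean Sq"]]
  mse <- ms[length(ms)]
  if (!is.finite(mse) || mse <= 0) return(c(0.1, 0.1))
  n_a <- mean(table(species))
  n_b <- mean(table(sex))
  g <- c(max(0, (ms[1] - mse) / (n_a * mse)),
         max(0, (ms[2] - mse) / (n_b * mse)))
  pmin(g, 1e4)
}

#' REML variance decomposition of one gene's expression
#'
#' Fits `y = mu + u_species + v_sex + e` with independent zero-mean
#' random effects by restricted maximum likelihood (residual variance
#' profiled out, variance ratios optimized under nonnegativity
#' constraints, relative tolerance 1e-8, at most 500 iterations) and
#' returns the variance fractions.
#'
#' @param y Numeric response (normalized log2 expression), length >= 4.
#' @param species,sex Factors/labels per observation; species must have
#'   2 levels.
#'
#' @return List of class `variance_fractions`: `frac_species`,
#'   `frac_sex`, `frac_residual` (summing to 1), `converged`, `n_iter`.
#' @export
fit_gene_lmm <- function(y, species, sex) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n >= 4L, length(species) == n, length(sex) == n)
  species <- factor(species); sex <- factor(sex)
  if (nlevels(species) < 2L) stop("species needs at least 2 levels")
  if (stats::var(y) < 1e-12 * max(mean(y)^2, 1)) {
    return(structure(list(frac_species = 0, frac_sex = 0,
                          frac_residual = 1, converged = TRUE,
                          n_iter = 0L),
                     class = "variance_fractions"))
  }
  # Degenerate rule: with an (essentially) perfect two-factor fit the
  # REML likelihood is unbounded in the variance ratios, so return the
  # ANOVA (method-of-moments) decomposition with zero residual.
  ols <- stats::lm(y ~ species + sex)
  if (stats::deviance(ols) <
        1e-10 * sum((y - mean(y))^2)) {
    an <- suppressWarnings(stats::anova(ols))
    ms <- an[["Mean Sq"]]
    sa <- ms[1] / mean(table(species))
    sb <- ms[2] / mean(table(sex))
    tot <- sa + sb
    return(structure(list(frac_species = sa / tot, frac_sex = sb / tot,
                          frac_residual = 0, converged = TRUE,
                          n_iter = 0L),
                     class = "variance_fractions"))
  }
  ys <- y / stats::sd(y) # scale-free criterion, better conditioning
  za <- stats::model.matrix(~ species - 1)
  zb <- stats::model.matrix(~ sex - 1)
  opt <- stats::nlminb(.mom_start(ys, species, sex), .reml_crit,
                       y = ys, za = za, zb = zb,
                       lower = c(0, 0), upper = c(1e8, 1e8),
                       control = list(rel.tol = 1e-10, iter.max = 500))
  g <- opt$par
  tot <- 1 + g[1] + g[2]
  structure(list(frac_species = g[1] / tot,
                 frac_sex = g[2] / tot,
                 frac_residual = 1 / tot,
                 converged = opt$convergence == 0 &&
                   opt$iterations <= 500,
                 n_iter = opt$iterations),
            class = "variance_fractions")
}

#' Variance decomposition for every gene of a study
#'
#' @param study A normalized [expression_study].
#'
#' @return data.frame with `gene_id`, `frac_species`, `frac_sex`,
#'   `frac_residual`, `converged`, `n_iter`, sorted by `gene_id`.
#' @export
variance_partition <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(study$normalized)) stop("run normalize_log() first")
  x <- study$normalized
  sp <- study$samples$species
  sx <- study$samples$sex
  rows <- lapply(seq_len(nrow(x)), function(g) {
    f <- fit_gene_lmm(x[g, ], sp, sx)
    data.frame(gene_id = rownames(x)[g],
               frac_species = f$frac_species, frac_sex = f$frac_sex,
               frac_residual = f$frac_residual,
               converged = f$converged, n_iter = f$n_iter,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen for genes dominated by interspecific variance
#'
#' Selects genes whose species variance fraction is at least
#' `threshold` (inclusive) and assigns each a direction from the sign
#' of the species mean difference on the normalized scale; exact ties
#' are excluded with a warning.
#'
#' @param fractions Output of [variance_partition].
#' @param study The normalized [expression_study] used for direction.
#' @param threshold Species-fraction threshold (default 0.80).
#'
#' @return data.frame with `gene_id`, `frac_species`, `selected`,
#'   `direction` (`"up_in_A"`, `"up_in_B"`, or `NA` for unselected
#'   genes).
#' @export
variance_screen <- function(fractions, study, threshold = 0.80) {
  stopifnot(inherits(study, "expression_study"))
  means <- species_gene_means(study)
  m <- merge(fractions, means, by = "gene_id")
  m <- m[order(m$gene_id), , drop = FALSE]
  sel <- m$frac_species >= threshold
  dir <- ifelse(m$mean_a > m$mean_b, "up_in_A",
                ifelse(m$mean_a < m$mean_b, "up_in_B", NA))
  tied <- sel & is.na(dir)
  if (any(tied)) {
    warning(sum(tied), " selected gene(s) with exactly equal species",
            " means excluded from the screen")
    sel[tied] <- FALSE
  }
  data.frame(gene_id = m$gene_id, frac_species = m$frac_species,
             selected = sel,
             direction = ifelse(sel, dir, NA_character_),
             stringsAsFactors = FALSE)
}
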