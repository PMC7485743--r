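# Pipeline orchestration: configuration, per-stage seed streams,
# stage execution, TSV outputs and a deterministic JSON summary.

#' Derive an independent per-stage seed from the master seed
#'
#' Hashes the stage label into the master seed with a multiplicative
#' congruential step so that adding a stage never perturbs another
#' stage's draws. Result is a positive integer below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stage Stage label (string).
#'
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) *
             seq_along(utf8ToInt(as.character(stage))))
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + h * 7919 + 1) %% m)
}

#' Pipeline configuration
#'
#' Collects input paths, thresholds and the master seed. Defaults
#' mirror the study's analysis settings: Ka/Ks FDR 0.05, minimum
#' alignment 100 bp, minimum coverage 0.8, DEG FDR 0.05, species
#' variance fraction threshold 0.8, enrichment FDR 0.05 with minimum
#' overlap 3, 20 top terms, 1000 subsampling draws, 95% HDI,
#' pseudocount 1.
#'
#' @param alignments,counts,samples,annotation,anti_list,pro_list
#'   Input file paths (see [make_fixture] for the formats); any of
#'   them may be `NULL` to skip the dependent stages.
#' @param out_dir Output directory.
#' @param seed Master seed recorded in every output.
#' @param kaks_fdr,min_len_bp,min_coverage Selection-scan settings.
#' @param de_fdr DEG FDR threshold (0.05 by default; the stricter 0.01
#'   variant is available through this knob).
#' @param varfrac_threshold Variance-screen threshold.
#' @param enrich_fdr,min_overlap,n_top_terms,term_fdr Ontology settings.
#' @param B,hdi_mass Subsampling-null settings.
#' @param pseudocount Added in the log2 transform.
#' @param filter_rule `"and"` (default) or `"or"`, see
#'   [filter_unexpressed].
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignments = NULL, counts = NULL,
                            samples = NULL, annotation = NULL,
                            anti_list = NULL, pro_list = NULL,
                            out_dir = "longbat_run", seed = 1L,
                            kaks_fdr = 0.05, min_len_bp = 100L,
                            min_coverage = 0.8, de_fdr = 0.05,
                            varfrac_threshold = 0.8,
                            enrich_fdr = 0.05, min_overlap = 3L,
                            n_top_terms = 20L, term_fdr = 0.05,
                            B = 1000L, hdi_mass = 0.95,
                            pseudocount = 1, filter_rule = "and") {
  cfg <- as.list(environment())
  stopifnot(kaks_fdr > 0, kaks_fdr < 1, de_fdr > 0, de_fdr < 1,
            varfrac_threshold >= 0, varfrac_threshold <= 1,
            enrich_fdr > 0, enrich_fdr < 1, min_overlap >= 1,
            n_top_terms >= 1, B >= 1, hdi_mass > 0, hdi_mass <= 1,
            pseudocount >= 0, min_len_bp >= 1,
            min_coverage >= 0, min_coverage <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys match the arguments of [pipeline_config]; relative input paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#'
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  for (k in c("alignments", "counts", "samples", "annotation",
              "anti_list", "pro_list")) {
    if (!is.null(raw[[k]]) && !startsWith(raw[[k]], "/")) {
      raw[[k]] <- file.path(base, raw[[k]])
    }
  }
  do.call(pipeline_config, raw)
}

.stage_msg <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

.round6 <- function(x) {
  if (is.numeric(x)) round(x, 6) else x
}

#' Run the full comparative longevity pipeline
#'
#' Executes, in order: the pairwise Ka/Ks selection scan; expression
#' filtering, TMM normalization, correlation structure and rank-based
#' differential expression; the selection-vs-expression association
#' tests; the REML variance screen; direction-specific GO
#' over-representation, top-term selection and term-level paired
#' tests; and the anti-/pro-longevity signature tests against the
#' gene-subsampling null. All stage tables are written as TSV (ids
#' sorted lexicographically) plus a JSON summary; identical config and
#' seed give identical outputs.
#'
#' @param config A [pipeline_config].
#'
#' @return The summary list, invisibly (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (k in c("alignments", "counts", "samples", "annotation",
              "anti_list", "pro_list")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      stop("input file missing: ", k, " = ", config[[k]])
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(schema_version = "1", seed = config$seed,
                  thresholds = lapply(
                    config[c("kaks_fdr", "min_len_bp", "min_coverage",
                             "de_fdr", "varfrac_threshold",
                             "enrich_fdr", "min_overlap",
                             "n_top_terms", "term_fdr", "B",
                             "hdi_mass", "pseudocount")],
                    .round6))

  # --- selection scan -------------------------------------------------
  kaks <- NULL
  if (!is.null(config$alignments)) {
    .stage_msg("selection: Ka/Ks scan")
    aln <- read_codon_alignments(config$alignments)
    kaks <- selection_scan(aln, kaks_fdr = config$kaks_fdr,
                           min_len_bp = config$min_len_bp,
                           min_coverage = config$min_coverage)
    write_tsv(kaks, file.path(config$out_dir, "kaks_scan.tsv"))
    def <- !is.na(kaks$omega)
    summary$selection <- lapply(list(
      n_genes = nrow(kaks),
      n_positive = sum(kaks$classification == "positive"),
      n_purifying = sum(kaks$classification == "purifying"),
      n_omega_gt1 = sum(def & kaks$omega > 1),
      median_omega = stats::median(kaks$omega[def]),
      prop_purifying_pct =
        100 * mean(kaks$classification == "purifying")), .round6)
    summary$selection$psg <-
      kaks$gene_id[kaks$classification == "positive"]
  }

  # --- expression -----------------------------------------------------
  study <- de <- means <- NULL
  if (!is.null(config$counts) && !is.null(config$samples)) {
    .stage_msg("expression: filter, TMM, correlations, DE")
    counts <- read_counts(config$counts)
    samples <- read_samples(config$samples)
    study <- expression_study(counts, samples)
    n_before <- nrow(study$counts)
    study <- filter_unexpressed(study, rule = config$filter_rule)
    study <- normalize_log(study, pseudocount = config$pseudocount)
    write_matrix_tsv(
      study$normalized[order(rownames(study$normalized)), ,
                       drop = FALSE],
      file.path(config$out_dir, "normalized.tsv"))
    corr <- correlation_analysis(study)
    write_matrix_tsv(corr$matrix,
                     file.path(config$out_dir, "correlation.tsv"),
                     id_col = "sample_id")
    de <- differential_expression(study, fdr_threshold = config$de_fdr)
    write_tsv(de, file.path(config$out_dir, "de.tsv"))
    means <- species_gene_means(study)
    summary$expression <- lapply(list(
      n_genes_input = n_before,
      n_genes_expressed = nrow(study$counts),
      n_excluded = n_before - nrow(study$counts),
      median_rho_intra = corr$median_intra,
      median_rho_inter = corr$median_inter,
      intra_vs_inter_p = corr$test$p_value,
      n_deg = sum(de$is_DEG),
      n_deg_up_a = sum(de$is_DEG & de$log2fc > 0),
      n_deg_up_b = sum(de$is_DEG & de$log2fc < 0)), .round6)
  }

  # --- selection vs expression association ----------------------------
  if (!is.null(kaks) && !is.null(de)) {
    .stage_msg("association: Ka/Ks vs differential expression")
    assoc <- selection_expression_association(de, kaks)
    summary$association <- lapply(list(
      ks_p = assoc$ks$p_value,
      chi2_p = assoc$chi2$p_value), .round6)
  }

  # --- variance screen ------------------------------------------------
  screen <- NULL
  if (!is.null(study)) {
    .stage_msg("variance_partition: per-gene REML + screen")
    fractions <- variance_partition(study)
    screen <- variance_screen(fractions, study,
                              threshold = config$varfrac_threshold)
    out <- merge(fractions, screen[, c("gene_id", "selected",
                                       "direction")], by = "gene_id")
    write_tsv(out[order(out$gene_id), ],
              file.path(config$out_dir, "variance_screen.tsv"))
    summary$variance <- lapply(list(
      mean_frac_species_pct = 100 * mean(fractions$frac_species),
      n_selected = sum(screen$selected),
      n_up_in_a = sum(screen$selected &
                        screen$direction == "up_in_A", na.rm = TRUE),
      n_up_in_b = sum(screen$selected &
                        screen$direction == "up_in_B", na.rm = TRUE)),
      .round6)
  }

  # --- ontology -------------------------------------------------------
  term_tests <- NULL
  if (!is.null(screen) && !is.null(config$annotation)) {
    .stage_msg("ontology: enrichment + term-level tests")
    ann <- read_annotation(config$annotation)
    background <- rownames(study$counts)
    fg_a <- screen$gene_id[screen$selected &
                             screen$direction == "up_in_A"]
    fg_b <- screen$gene_id[screen$selected &
                             screen$direction == "up_in_B"]
    enr_a <- hypergeom_enrich(fg_a, background, ann,
                              fdr_threshold = config$enrich_fdr,
                              min_overlap = config$min_overlap)
    enr_b <- hypergeom_enrich(fg_b, background, ann,
                              fdr_threshold = config$enrich_fdr,
                              min_overlap = config$min_overlap)
    write_tsv(enr_a, file.path(config$out_dir, "enrichment_up_a.tsv"))
    write_tsv(enr_b, file.path(config$out_dir, "enrichment_up_b.tsv"))
    top <- select_top_terms(enr_a, enr_b, k = config$n_top_terms)
    term_tests <- term_expression_test(means, top$term_id, ann,
                                       fdr_threshold = config$term_fdr)
    write_tsv(term_tests, file.path(config$out_dir, "term_tests.tsv"))
    summary$ontology <- list(
      n_enriched_up_a = sum(enr_a$enriched),
      n_enriched_up_b = sum(enr_b$enriched),
      n_top_terms = nrow(top),
      n_terms_higher_in_a =
        sum(term_tests$call == "higher_in_A"),
      n_terms_higher_in_b =
        sum(term_tests$call == "higher_in_B"),
      terms_higher_in_a =
        term_tests$term_id[term_tests$call == "higher_in_A"])
  }

  # --- longevity signature --------------------------------------------
  if (!is.null(means) && !is.null(screen) &&
      (!is.null(config$anti_list) || !is.null(config$pro_list))) {
    .stage_msg("longevity_signature: list tests + subsampling null")
    background <- screen$gene_id[screen$selected]
    summary$signature <- list()
    for (side in c("anti", "pro")) {
      lp <- config[[paste0(side, "_list")]]
      if (is.null(lp)) next
      gl <- read_gene_list(lp)
      alt <- if (side == "anti") "less" else "greater"
      obs <- signature_test(means, gl, alternative = alt)
      n_used <- attr(obs, "n_genes")
      null <- subsample_null(
        means, background, list_size = n_used, B = config$B,
        seed = derive_seed(config$seed, paste0("null_", side)),
        alternative = alt, hdi_mass = config$hdi_mass)
      dec <- signature_call(obs, null)
      summary$signature[[side]] <- lapply(list(
        n_genes = n_used, observed_p = obs$p_value,
        hdi_lower = null$hdi$lower, hdi_upper = null$hdi$upper,
        call = dec$call), .round6)
    }
  }

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(config$out_dir, "summary.json"))
  invisible(summary)
}

#' Check a pipeline summary against the bundled schema
#'
#' Verifies the required top-level fields of a `summary.json` (schema
#' `inst/schema/summary-schema-v1.json`).
#'
#' @param summary Summary list or path to a summary JSON file.
#'
#' @return `TRUE` (invisibly) or an error naming the missing field.
#' @export
validate_summary <- function(summary) {
  if (is.character(summary)) {
    summary <- jsonlite::read_json(summary, simplifyVector = TRUE)
  }
  schema <- jsonlite::read_json(
    system.file("schema", "summary-schema-v1.json",
                package = "longbat"),
    simplifyVector = TRUE)
  if (!identical(as.character(summary$schema_version),
                 schema$version)) {
    stop("summary schema version mismatch")
  }
  miss <- setdiff(schema$required, names(summary))
  if (length(miss) > 0L) {
    stop("summary missing fields: ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
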