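# Plain-text readers/writers for the pipeline's tabular formats.

#' Read a gene x sample count matrix from TSV
#'
#' First column = gene ids, header = sample ids.
#'
#' @param path TSV file path.
#' @return Integer matrix with dimnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Write a gene x sample matrix to TSV
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the id column (default `"gene_id"`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata TSV (`sample_id`, `species`, `sex`, ...)
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_samples <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a gene-to-term annotation TSV
#' (`gene_id`, `term_id`, optional `term_name`)
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a one-id-per-line gene list
#' @param path Text file path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write a data.frame to TSV
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
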