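#' Read and write expression matrices as TSV
#'
#' Matrices are stored with the row-id column first (`probe_id` or
#' `gene_id`) and one column per sample; all signals on the log2 scale
#' unless a file is explicitly declared linear (raw background-corrected
#' input).
#'
#' @param matrix numeric matrix with row and column names.
#' @param path file path.
#' @param id_col name of the id column.
#' @export
write_matrix_tsv <- function(matrix, path, id_col = "probe_id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @return `read_matrix_tsv()` returns a numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read/write the sample sheet
#' @param sheet sample sheet data.frame.
#' @param path file path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "experiment", "timepoint") %in% names(df))) {
    stop("sample sheet must have sample_id, experiment, timepoint columns")
  }
  df
}

#' Read/write ground-truth tables
#' @param truth truth data.frame from [simulate_expression()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a gene list (one id per line)
#' @param path file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' @rdname read_gene_list
#' @param genes character vector of gene ids.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
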