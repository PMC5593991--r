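# TSV read/write helpers for the pipeline's file interfaces.

#' Write/read a probe x sample matrix as TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path file path.
#' @rdname matrix_tsv
#' @export
write_matrix_tsv <- function(mat, path) {
  utils::write.table(data.frame(probe = rownames(mat), mat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write/read a long-format table as TSV
#'
#' @param x data.frame.
#' @param path file path.
#' @rdname table_tsv
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Write all files of an expression experiment (matrix, sample sheet, truth)
#'
#' @param exp an `expression_experiment`.
#' @param dir output directory (created if missing).
#' @export
write_expression_tsv <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(exp$matrix, file.path(dir, "expression_matrix.tsv"))
  write_table_tsv(exp$samples, file.path(dir, "sample_sheet.tsv"))
  write_table_tsv(exp$truth$spiked, file.path(dir, "spiked_truth.tsv"))
  invisible(dir)
}
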