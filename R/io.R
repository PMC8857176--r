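# Table readers/writers shared by the pipeline stages. All tables written
# here re-parse losslessly through the matching reader.

#' Write / read a cells x features count matrix as TSV
#'
#' Cells are rows; the first column (`cell`) holds cell ids.
#'
#' @param m matrix with dimnames.
#' @param path TSV path.
#' @return The path / the matrix.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(cell = rownames(m), as.data.frame(unclass(m),
                                                     check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a count matrix as MatrixMarket MTX with name sidecars
#'
#' Writes `<path>` (MTX), `<path>.rows` and `<path>.cols` (one name per
#' line).
#'
#' @param m matrix with dimnames.
#' @param path `.mtx` path.
#' @return The path / the dense matrix.
#' @export
write_count_mtx <- function(m, path) {
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  writeLines(rownames(m), paste0(path, ".rows"))
  writeLines(colnames(m), paste0(path, ".cols"))
  invisible(path)
}

#' @rdname write_count_mtx
#' @export
read_count_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(paste0(path, ".rows"))
  colnames(m) <- readLines(paste0(path, ".cols"))
  m
}

#' Read / write a genes x cells mRNA expression matrix as TSV
#'
#' Genes are rows; the first column (`gene`) holds gene ids.
#'
#' @param mrna matrix / path.
#' @param path TSV path.
#' @return The path / the matrix.
#' @export
write_mrna_matrix <- function(mrna, path) {
  df <- data.frame(gene = rownames(mrna),
                   as.data.frame(unclass(mrna), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mrna_matrix
#' @export
read_mrna_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write a miRNA target prediction table (TSV)
#'
#' Columns: mirna, gene, source, rank.
#'
#' @param targets data.frame / path.
#' @param path TSV path.
#' @return The path / the data.frame.
#' @export
write_target_table <- function(targets, path) {
  utils::write.table(targets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_target_table
#' @export
read_target_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
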