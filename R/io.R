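#' Read and write feature matrices and metadata tables
#'
#' Matrices travel as TSV with feature identifiers in the first column and
#' sample identifiers as column names; counts may also arrive as MatrixMarket
#' triplets with sidecar row/column name files. Metadata are plain TSV with
#' a header row.
#'
#' @param path file path
#' @return `read_matrix_tsv` returns a numeric matrix with dimnames
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param mat matrix to write
#' @param id_name header for the feature-identifier column
#' @export
write_matrix_tsv <- function(mat, path, id_name = "feature") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_matrix_tsv
#' @export
read_meta_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_matrix_tsv
#' @param df data.frame to write
#' @export
write_meta_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts matrix from MatrixMarket triplet files
#'
#' @param mtx_path MatrixMarket coordinate file
#' @param rownames_path,colnames_path one identifier per line
#' @return dense numeric matrix
#' @export
read_matrix_mtx <- function(mtx_path, rownames_path, colnames_path) {
  lines <- readLines(mtx_path)
  lines <- lines[!grepl("^%", lines)]
  hdr <- scan(text = lines[1], quiet = TRUE)
  body <- utils::read.table(text = lines[-1])
  m <- matrix(0, hdr[1], hdr[2])
  m[cbind(body[[1]], body[[2]])] <- body[[3]]
  rownames(m) <- readLines(rownames_path)
  colnames(m) <- readLines(colnames_path)
  m
}
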