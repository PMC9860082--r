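#' Read a UMI count matrix
#'
#' `"mtx"` reads a Matrix Market directory (or a `.mtx` file path) with
#' its `genes.tsv` / `barcodes.tsv` sidecars; matrices are stored
#' cells-as-rows. `"dense"` reads a delimited matrix with cell ids in the
#' first column and gene ids in the header.
#'
#' @param path directory containing `matrix.mtx` + sidecars (or the
#'   `.mtx` file itself) for `"mtx"`; a delimited file for `"dense"`
#' @param format `"mtx"` or `"dense"`
#' @param sep field separator for `"dense"` (default tab)
#' @return a `dgCMatrix` of counts, cells x genes, with unique cell and
#'   gene identifiers as dimnames
#' @export
read_counts <- function(path, format = c("mtx", "dense"), sep = "\t") {
  format <- match.arg(format)
  if (format == "mtx") {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
    genes_f <- file.path(dir, "genes.tsv")
    barcodes_f <- file.path(dir, "barcodes.tsv")
    for (f in c(mtx, genes_f, barcodes_f))
      if (!file.exists(f)) stopf("file not found: %s", f)
    m <- as_dgc(Matrix::readMM(mtx))
    genes <- readLines(genes_f)
    barcodes <- readLines(barcodes_f)
    if (length(barcodes) != nrow(m) || length(genes) != ncol(m))
      stopf("sidecar mismatch: matrix is %d cells x %d genes but barcodes.tsv has %d and genes.tsv has %d entries",
            nrow(m), ncol(m), length(barcodes), length(genes))
    if (anyDuplicated(barcodes))
      stopf("barcodes.tsv contains %d duplicated cell id(s)",
            sum(duplicated(barcodes)))
    if (anyDuplicated(genes))
      stopf("genes.tsv contains %d duplicated gene id(s)",
            sum(duplicated(genes)))
    dimnames(m) <- list(barcodes, genes)
  } else {
    df <- utils::read.delim(path, sep = sep, header = TRUE,
                            row.names = 1L, check.names = FALSE)
    if (anyDuplicated(rownames(df)))
      stopf("duplicated cell id(s) in %s", path)
    m <- as_dgc(as.matrix(df))
  }
  assert_count_matrix(m)
}

#' Write a UMI count matrix
#'
#' Inverse of [read_counts()]: `"mtx"` writes `matrix.mtx`, `genes.tsv`
#' and `barcodes.tsv` into `path` (a directory, created if needed);
#' `"dense"` writes a single delimited table.
#'
#' @param counts cells x genes count matrix with dimnames
#' @inheritParams read_counts
#' @return `path`, invisibly
#' @export
write_counts <- function(counts, path, format = c("mtx", "dense"),
                         sep = "\t") {
  format <- match.arg(format)
  counts <- assert_count_matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("'counts' must carry cell and gene identifiers as dimnames")
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(counts, file.path(path, "matrix.mtx"))
    writeLines(colnames(counts), file.path(path, "genes.tsv"))
    writeLines(rownames(counts), file.path(path, "barcodes.tsv"))
  } else {
    df <- as.data.frame(as.matrix(counts), check.names = FALSE)
    df <- cbind(cell_id = rownames(counts), df)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a per-cell label or metadata table
#'
#' Two-or-more-column tab-separated tables with a header; the first
#' column is the cell id.
#'
#' @param path file path
#' @return `read_cell_table()`: a data.frame; `write_cell_table()`:
#'   `path`, invisibly
#' @export
read_cell_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L)
    stopf("'%s' must have at least a cell id column and one value column",
          path)
  df
}

#' @rdname read_cell_table
#' @param df data.frame whose first column is the cell id
#' @export
write_cell_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
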