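# Internal argument checking. Errors name the offending field so that
# spec-style validation messages are actionable.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# canonical internal representation: numeric CsparseMatrix, cells x genes
as_dgc <- function(m) {
  if (!methods::is(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
}

assert_scalar_number <- function(x, field, positive = FALSE,
                                 nonneg = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", field)
  if (integer && x != round(x))
    stopf("'%s' must be an integer", field)
  if (positive && x <= 0)
    stopf("'%s' must be strictly positive", field)
  if (nonneg && x < 0)
    stopf("'%s' must be non-negative", field)
  invisible(x)
}

#' Check that a matrix is a valid cells-by-genes UMI count matrix
#' @param counts matrix or Matrix of non-negative integers
#' @return the matrix, coerced to `dgCMatrix`, invisibly usable downstream
#' @noRd
assert_count_matrix <- function(counts) {
  if (!(is.matrix(counts) || methods::is(counts, "Matrix")))
    stopf("'counts' must be a matrix of UMI counts (cells x genes)")
  x <- if (methods::is(counts, "sparseMatrix")) counts@x else as.vector(counts)
  if (length(x) && (any(!is.finite(x)) || any(x < 0)))
    stopf("'counts' must be non-negative and finite")
  if (length(x) && any(x != round(x)))
    stopf("'counts' must contain integer UMI counts")
  as_dgc(counts)
}

# dense numeric submatrix of a (possibly sparse) expression matrix
dense_submatrix <- function(mat, genes) {
  missing <- setdiff(genes, colnames(mat))
  if (length(missing))
    stopf("%d feature(s) missing from the matrix: %s", length(missing),
          paste(utils::head(missing, 5L), collapse = ", "))
  as.matrix(mat[, genes, drop = FALSE])
}
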