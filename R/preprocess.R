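#' QC thresholds for cell and gene filtering
#'
#' Container for the filters applied by [filter_cells()]. The defaults
#' (1,000 UMIs and 500 detected genes per cell) are ordinary droplet-data
#' starting points, not values taken from any particular study;
#' mitochondrial filtering is off unless a mito gene list is supplied.
#'
#' @param min_umis_per_cell minimum total UMI count per retained cell
#' @param min_genes_per_cell minimum number of detected (count > 0) genes
#' @param max_mito_fraction optional maximum fraction of counts in
#'   `mito_genes`; requires `mito_genes`
#' @param mito_genes character vector of mitochondrial gene identifiers
#' @param min_cells_per_gene minimum number of retained cells a gene must
#'   be detected in
#' @return an object of class `scw_qc_thresholds`
#' @export
qc_thresholds <- function(min_umis_per_cell = 1000L,
                          min_genes_per_cell = 500L,
                          max_mito_fraction = NULL,
                          mito_genes = NULL,
                          min_cells_per_gene = 0L) {
  assert_scalar_number(min_umis_per_cell, "min_umis_per_cell",
                       nonneg = TRUE, integer = TRUE)
  assert_scalar_number(min_genes_per_cell, "min_genes_per_cell",
                       nonneg = TRUE, integer = TRUE)
  assert_scalar_number(min_cells_per_gene, "min_cells_per_gene",
                       nonneg = TRUE, integer = TRUE)
  if (!is.null(max_mito_fraction)) {
    assert_scalar_number(max_mito_fraction, "max_mito_fraction",
                         nonneg = TRUE)
    if (max_mito_fraction > 1)
      stopf("'max_mito_fraction' must lie in [0, 1]")
    if (is.null(mito_genes))
      stopf("'max_mito_fraction' requires 'mito_genes'")
  }
  structure(list(
    min_umis_per_cell = as.integer(min_umis_per_cell),
    min_genes_per_cell = as.integer(min_genes_per_cell),
    max_mito_fraction = max_mito_fraction,
    mito_genes = mito_genes,
    min_cells_per_gene = as.integer(min_cells_per_gene)
  ), class = "scw_qc_thresholds")
}

#' Filter cells and genes of a UMI count matrix
#'
#' Cells are filtered first, on the full gene set: a cell is retained when
#' its total UMIs, detected genes and (optionally) mitochondrial fraction
#' all pass the thresholds. Genes are then filtered on the retained cells
#' only (`min_cells_per_gene`); cell totals are not recomputed after gene
#' removal.
#'
#' @param counts cells x genes matrix of non-negative integer UMI counts
#' @param thresholds a [qc_thresholds()] object
#' @param groups optional per-cell categorical (e.g. time point or line);
#'   the report then includes per-group means of UMIs and detected genes
#'   among retained cells
#' @return list with `counts` (the filtered matrix) and `report`, a list
#'   of class `scw_qc_report` recording per-criterion removal counts and
#'   optional per-group summaries
#' @examples
#' m <- Matrix::Matrix(matrix(rpois(50, 5), 5, 10, dimnames = list(
#'   paste0("c", 1:5), paste0("g", 1:10))), sparse = TRUE)
#' filter_cells(m, qc_thresholds(min_umis_per_cell = 0,
#'                               min_genes_per_cell = 0))$report
#' @export
filter_cells <- function(counts, thresholds = qc_thresholds(),
                         groups = NULL) {
  counts <- assert_count_matrix(counts)
  if (!inherits(thresholds, "scw_qc_thresholds"))
    stopf("'thresholds' must be created by qc_thresholds()")
  if (!is.null(groups) && length(groups) != nrow(counts))
    stopf("'groups' must have one entry per cell")
  umis <- Matrix::rowSums(counts)
  ngenes <- Matrix::rowSums(counts > 0)
  keep_umi <- umis >= thresholds$min_umis_per_cell
  keep_genes <- ngenes >= thresholds$min_genes_per_cell
  keep_mito <- rep(TRUE, nrow(counts))
  if (!is.null(thresholds$max_mito_fraction)) {
    mito <- intersect(thresholds$mito_genes, colnames(counts))
    mito_frac <- if (length(mito))
      Matrix::rowSums(counts[, mito, drop = FALSE]) / pmax(umis, 1) else 0
    keep_mito <- mito_frac <= thresholds$max_mito_fraction
  }
  keep_cell <- keep_umi & keep_genes & keep_mito
  if (!any(keep_cell))
    warnf("no cells pass the QC thresholds")
  kept <- counts[keep_cell, , drop = FALSE]
  gene_support <- Matrix::colSums(kept > 0)
  keep_gene <- gene_support >= thresholds$min_cells_per_gene
  kept <- kept[, keep_gene, drop = FALSE]
  report <- list(
    n_cells_in = nrow(counts),
    n_cells_out = nrow(kept),
    removed_low_umis = sum(!keep_umi),
    removed_few_genes = sum(!keep_genes),
    removed_high_mito = sum(!keep_mito),
    n_genes_in = ncol(counts),
    n_genes_out = ncol(kept),
    removed_genes_low_support = sum(!keep_gene),
    thresholds = thresholds
  )
  if (!is.null(groups)) {
    g <- factor(groups)[keep_cell]
    report$group_summary <- data.frame(
      group = levels(g),
      n_cells = as.integer(table(g)),
      mean_umis = as.numeric(tapply(umis[keep_cell], g, mean)),
      mean_genes = as.numeric(tapply(ngenes[keep_cell], g, mean)),
      row.names = NULL
    )
  }
  class(report) <- "scw_qc_report"
  list(counts = kept, report = report)
}

#' @export
print.scw_qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d/%d cells retained, %d/%d genes retained\n",
              x$n_cells_out, x$n_cells_in, x$n_genes_out, x$n_genes_in))
  cat(sprintf("  removed: %d low-UMI, %d few-gene, %d high-mito cells; %d low-support genes\n",
              x$removed_low_umis, x$removed_few_genes,
              x$removed_high_mito, x$removed_genes_low_support))
  if (!is.null(x$group_summary)) print(x$group_summary)
  invisible(x)
}

#' Log-library-size normalization
#'
#' The standard scRNA-seq normalization: each entry becomes
#' `ln(1 + scale_factor * count / library_size)`, where the library size is
#' the cell's total UMI count. Zeros map exactly to zeros and the map is
#' strictly increasing in the count within a cell.
#'
#' @param counts cells x genes matrix of non-negative integer UMI counts
#' @param scale_factor pseudo library size every cell is rescaled to
#'   (default 10,000)
#' @return a `dgCMatrix` of normalized expression with the same dimnames;
#'   the scale factor is attached as attribute `"scale_factor"`
#' @examples
#' m <- Matrix::Matrix(matrix(c(0, 5, 5), 1, 3,
#'   dimnames = list("c1", c("a", "b", "c"))), sparse = TRUE)
#' normalize_log_library(m, scale_factor = 10)  # 0, log(6), log(6)
#' @export
normalize_log_library <- function(counts, scale_factor = 1e4) {
  counts <- assert_count_matrix(counts)
  assert_scalar_number(scale_factor, "scale_factor", positive = TRUE)
  libsize <- Matrix::rowSums(counts)
  if (nrow(counts) && any(libsize == 0)) {
    bad <- rownames(counts)[which(libsize == 0)]
    if (is.null(bad)) bad <- which(libsize == 0)
    stopf("cell(s) with zero library size cannot be normalized: %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  norm <- counts
  if (length(norm@x)) {
    # transform the nonzero slots in place: sparsity pattern is preserved
    cell_of <- norm@i + 1L  # dgCMatrix row indices of the nonzeros
    norm@x <- log1p(scale_factor * norm@x / libsize[cell_of])
  }
  attr(norm, "scale_factor") <- scale_factor
  norm
}

#' Select the feature (gene) space shared by reference and query
#'
#' @param ref_genes,query_genes gene identifier vectors of the two data
#'   sets
#' @param mode `"intersection"` (sorted common genes), `"hvg"` (top-`k`
#'   common genes by variance of normalized expression in the reference)
#'   or `"markers"` (a user panel intersected with both universes)
#' @param k number of highly variable genes for `mode = "hvg"`; clamped to
#'   the intersection size with a warning
#' @param ref_norm normalized reference matrix, required for `"hvg"`
#' @param panel gene panel, required for `"markers"`
#' @return character vector of selected genes with attribute `"method"`
#' @export
select_features <- function(ref_genes, query_genes,
                            mode = c("intersection", "hvg", "markers"),
                            k = NULL, ref_norm = NULL, panel = NULL) {
  mode <- match.arg(mode)
  if (!length(ref_genes) || !length(query_genes))
    stopf("gene lists must be non-empty")
  common <- sort(intersect(ref_genes, query_genes))
  if (!length(common))
    stopf("reference and query share no genes")
  feats <- switch(mode,
    intersection = common,
    hvg = {
      if (is.null(ref_norm) || is.null(k))
        stopf("mode 'hvg' requires 'ref_norm' and 'k'")
      if (k > length(common)) {
        warnf("k = %d exceeds the %d common genes; returning all of them",
              k, length(common))
        k <- length(common)
      }
      sub <- ref_norm[, common, drop = FALSE]
      v <- apply(as.matrix(sub), 2L, var)
      common[order(-v, seq_along(v))][seq_len(k)]
    },
    markers = {
      if (is.null(panel)) stopf("mode 'markers' requires 'panel'")
      out <- panel[panel %in% common]
      if (!length(out)) stopf("no panel gene is shared by both data sets")
      unique(out)
    })
  structure(feats, method = mode)
}
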