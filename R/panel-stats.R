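#' Gene-panel expression score
#'
#' The panel statistic used throughout: the sum, over the panel's genes,
#' of each gene's mean normalized expression across the chosen cells. A
#' cell-cycle panel turns it into a proliferation index; a reference-type
#' marker panel turns it into the statistic tested by
#' [permutation_test_panel()].
#'
#' @param norm cells x genes normalized expression matrix
#' @param panel character vector of gene identifiers; genes absent from
#'   the matrix are dropped with a warning and recorded in the result
#' @param cells cell identifiers or indices defining the cell set
#'   (default: all cells)
#' @return a list of class `scw_panel_score`: `statistic`, `panel_used`,
#'   `panel_dropped`, `n_cells`
#' @export
score_gene_panel <- function(norm, panel, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(norm))
  sub <- norm[cells, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("'cells' selects no cells")
  present <- panel[panel %in% colnames(norm)]
  dropped <- setdiff(panel, present)
  if (length(dropped))
    warnf("%d panel gene(s) absent from the matrix: %s", length(dropped),
          paste(utils::head(dropped, 5L), collapse = ", "))
  if (!length(present)) stopf("no panel gene is present in the matrix")
  stat <- sum(Matrix::colMeans(sub[, present, drop = FALSE]))
  structure(list(statistic = stat, panel_used = present,
                 panel_dropped = dropped, n_cells = nrow(sub)),
            class = "scw_panel_score")
}

#' @export
print.scw_panel_score <- function(x, ...) {
  cat(sprintf("panel score: %.4f (%d genes, %d cells%s)\n", x$statistic,
              length(x$panel_used), x$n_cells,
              if (length(x$panel_dropped))
                sprintf(", %d genes dropped", length(x$panel_dropped))
              else ""))
  invisible(x)
}

#' Permutation test on a gene-panel expression sum
#'
#' Tests, one-sided, whether the panel statistic of [score_gene_panel()]
#' is higher in a focal cell group than expected under random group
#' membership: the alternative is that the sum of the panel genes' average
#' normalized expression is elevated in the focal cells. Group labels are
#' permuted across the pooled cells `n_perm` times (the permutation unit
#' is the cell, since the hypothesis concerns cell groups) and the
#' statistic recomputed on each permuted focal set of the original size.
#' The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so `p` is never 0 and
#' never below `1/(n_perm + 1)`.
#'
#' @param norm cells x genes normalized expression matrix
#' @param panel gene panel (see [score_gene_panel()])
#' @param focal_cells,comparison_cells disjoint, non-empty cell
#'   identifier/index vectors
#' @param n_perm number of permutations (default 1000)
#' @param seed integer seed for the permutations
#' @return a list of class `scw_perm_result`: `observed`, `null_stats`
#'   (length `n_perm`), `n_perm`, `p_value`, `seed`,
#'   `alternative = "greater"`
#' @export
permutation_test_panel <- function(norm, panel, focal_cells,
                                   comparison_cells, n_perm = 1000L,
                                   seed = 0L) {
  assert_scalar_number(n_perm, "n_perm", positive = TRUE, integer = TRUE)
  assert_scalar_number(seed, "seed", integer = TRUE)
  if (!length(focal_cells) || !length(comparison_cells))
    stopf("both cell groups must be non-empty")
  fi <- resolve_cells(norm, focal_cells, "focal_cells")
  ci <- resolve_cells(norm, comparison_cells, "comparison_cells")
  if (length(intersect(fi, ci)))
    stopf("focal and comparison cells overlap (%d cells)",
          length(intersect(fi, ci)))
  present <- panel[panel %in% colnames(norm)]
  if (!length(present)) stopf("no panel gene is present in the matrix")
  if (length(present) < length(panel))
    warnf("%d panel gene(s) absent from the matrix",
          length(panel) - length(present))
  pooled <- c(fi, ci)
  # per-cell panel totals: the group statistic is their mean, so the whole
  # null can be drawn by resampling this vector
  cell_scores <- Matrix::rowSums(norm[pooled, present, drop = FALSE])
  n_focal <- length(fi)
  observed <- mean(cell_scores[seq_len(n_focal)])
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i)
    mean(cell_scores[sample.int(length(pooled), n_focal)]), numeric(1))
  p <- (1 + sum(null_stats >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null_stats = null_stats,
                 n_perm = as.integer(n_perm), p_value = p,
                 seed = as.integer(seed), alternative = "greater",
                 panel_used = present),
            class = "scw_perm_result")
}

resolve_cells <- function(mat, cells, field) {
  if (is.character(cells)) {
    idx <- match(cells, rownames(mat))
    if (anyNA(idx))
      stopf("'%s' contains %d unknown cell id(s)", field, sum(is.na(idx)))
    idx
  } else {
    idx <- as.integer(cells)
    if (any(idx < 1L | idx > nrow(mat)))
      stopf("'%s' contains out-of-range indices", field)
    idx
  }
}

#' @export
print.scw_perm_result <- function(x, ...) {
  cat(sprintf("permutation test (greater): observed = %.4f, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Beta-posterior marker-enrichment call
#'
#' Asks whether a gene is detected more often in a focal cell type than in
#' the remaining cells. Detection (count >= `detection_cutoff`) in each
#' group is modeled as binomial with a Jeffreys Beta(1/2, 1/2) prior, and
#' the reported posterior probability is
#' `P(theta_focal > theta_rest | data)`, computed by numerical integration
#' of the two Beta posteriors. The gene is called enriched when the
#' posterior exceeds `threshold` (default 0.998, i.e. the ">99.8%"
#' convention used to flag enriched markers in atlas violin plots).
#'
#' @param counts cells x genes UMI count matrix
#' @param labels per-cell type labels
#' @param gene gene identifier to test
#' @param focal_type the type whose enrichment is tested
#' @param detection_cutoff minimum count for a cell to count as detecting
#'   the gene (default 1 UMI)
#' @param threshold posterior probability above which the gene is called
#'   enriched
#' @return a list of class `scw_enrichment`: `gene`, `focal_type`,
#'   `posterior`, `enriched`, `detection_focal`, `detection_rest`,
#'   `n_focal`, `n_rest`
#' @export
marker_enrichment <- function(counts, labels, gene, focal_type,
                              detection_cutoff = 1L, threshold = 0.998) {
  assert_scalar_number(detection_cutoff, "detection_cutoff",
                       positive = TRUE, integer = TRUE)
  assert_scalar_number(threshold, "threshold", positive = TRUE)
  if (threshold >= 1) stopf("'threshold' must be below 1")
  if (!gene %in% colnames(counts))
    stopf("gene '%s' not present in the matrix", gene)
  labels <- as.character(labels)
  if (length(labels) != nrow(counts))
    stopf("'labels' must have one entry per cell")
  if (!focal_type %in% labels)
    stopf("focal type '%s' not present in the labels", focal_type)
  focal <- labels == focal_type
  n_f <- sum(focal); n_r <- sum(!focal)
  if (n_r == 0L) stopf("no cells outside the focal type")
  det <- as.numeric(counts[, gene]) >= detection_cutoff
  s_f <- sum(det[focal]); s_r <- sum(det[!focal])
  post <- beta_greater_posterior(s_f + 0.5, n_f - s_f + 0.5,
                                 s_r + 0.5, n_r - s_r + 0.5)
  structure(list(gene = gene, focal_type = focal_type,
                 posterior = post, enriched = post > threshold,
                 detection_focal = s_f / n_f, detection_rest = s_r / n_r,
                 n_focal = n_f, n_rest = n_r,
                 detection_cutoff = as.integer(detection_cutoff),
                 threshold = threshold),
            class = "scw_enrichment")
}

# P(X > Y) for X ~ Beta(a1, b1), Y ~ Beta(a2, b2):
# integral over x of dbeta(x; a1, b1) * pbeta(x; a2, b2)
beta_greater_posterior <- function(a1, b1, a2, b2) {
  f <- function(x) dbeta(x, a1, b1) * pbeta(x, a2, b2)
  val <- integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
  min(max(val, 0), 1)
}

#' @export
print.scw_enrichment <- function(x, ...) {
  cat(sprintf("%s in %s: detected %.1f%% vs %.1f%%, P(enriched) = %.5f -> %s\n",
              x$gene, x$focal_type, 100 * x$detection_focal,
              100 * x$detection_rest, x$posterior,
              if (x$enriched) "enriched" else "not enriched"))
  invisible(x)
}
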