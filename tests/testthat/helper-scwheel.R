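# Shared fixtures: everything is generated in code, nothing on disk.

# a compact but well-separated atlas used across mapping/clustering tests
small_atlas <- function(n_types = 4, n_cells_per_type = 60, n_genes = 600,
                        log2fc = 3, seed = 42) {
  generate_atlas(atlas_spec(
    n_types = n_types, n_cells_per_type = n_cells_per_type,
    n_genes = n_genes, n_markers_per_type = 20,
    marker_log2fc = log2fc, seed = seed))
}

# dense count matrix with dimnames, for hand-built toy cases
toy_counts <- function(values, cells = NULL, genes = NULL) {
  m <- as.matrix(values)
  rownames(m) <- cells %||% paste0("c", seq_len(nrow(m)))
  colnames(m) <- genes %||% paste0("g", seq_len(ncol(m)))
  Matrix::Matrix(m, sparse = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a complete on-disk pipeline fixture: a 5-type reference and a query of
# three pure populations plus one mixed population
make_pipeline_inputs <- function(root, seed = 171) {
  atl <- generate_atlas(atlas_spec(n_types = 5, n_cells_per_type = 60,
                                   n_genes = 600, n_markers_per_type = 20,
                                   seed = seed))
  W <- rbind(program_weights(80, 1, 5), program_weights(80, 3, 5),
             program_weights(80, 5, 5), program_weights(60, c(2, 4), 5))
  q <- generate_query(atl$truth, query_spec(
    300, W, timepoint_labels = rep(c("d21", "d28"), 150),
    seed = seed + 1))
  ref_dir <- file.path(root, "ref"); query_dir <- file.path(root, "query")
  write_counts(atl$counts, ref_dir)
  write_counts(q$counts, query_dir)
  write_cell_table(data.frame(cell_id = rownames(atl$counts),
                              label = as.character(atl$labels)),
                   file.path(root, "ref_labels.tsv"))
  write_cell_table(data.frame(cell_id = rownames(q$counts),
                              timepoint = q$metadata$timepoint),
                   file.path(root, "query_meta.tsv"))
  pipeline_config(
    ref_counts = ref_dir,
    ref_labels = file.path(root, "ref_labels.tsv"),
    query_counts = query_dir,
    query_metadata = file.path(root, "query_meta.tsv"),
    output_dir = file.path(root, "out"),
    qc = qc_thresholds(min_umis_per_cell = 500, min_genes_per_cell = 50),
    d = 20, k = 15, n_perm = 200, seed = 7)
}
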