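#' Configure an end-to-end identity-scoring run
#'
#' Collects every parameter of [run_pipeline()]: input paths, QC
#' thresholds, normalization scale, clustering parameters, classifier
#' settings, similarity-band thresholds, permutation settings and the
#' global seed. Path existence is checked at run time, before any
#' computation.
#'
#' @param ref_counts path to the reference atlas counts (MTX directory or
#'   dense table, see `format`)
#' @param ref_labels path to a two-column TSV (cell_id, label) of
#'   reference cell types
#' @param query_counts path to the query counts
#' @param output_dir directory all outputs are written into
#' @param query_metadata optional path to a per-cell metadata TSV
#'   (cell_id plus e.g. timepoint / line columns)
#' @param format `"mtx"` or `"dense"` for both count inputs
#' @param qc a [qc_thresholds()] object applied to the query cells
#' @param scale_factor normalization pseudo library size
#' @param features_mode,hvg_k feature selection (see [select_features()])
#' @param d,k,resolution PCA dimensionality, kNN neighbors, Louvain
#'   resolution
#' @param l2_strength classifier ridge penalty
#' @param show_threshold,high_threshold similarity band edges (0.5 / 0.8)
#' @param n_perm permutations per gene-panel test
#' @param panel_size number of top-weight classifier genes forming each
#'   reference type's panel in the permutation tests
#' @param seed global integer seed; every stochastic stage derives its
#'   seed from it, so a full rerun is reproducible
#' @return an object of class `scw_pipeline_config`
#' @export
pipeline_config <- function(ref_counts, ref_labels, query_counts,
                            output_dir, query_metadata = NULL,
                            format = c("mtx", "dense"),
                            qc = qc_thresholds(),
                            scale_factor = 1e4,
                            features_mode = "intersection", hvg_k = NULL,
                            d = 50L, k = 15L, resolution = 1,
                            l2_strength = 1,
                            show_threshold = 0.5, high_threshold = 0.8,
                            n_perm = 1000L, panel_size = 20L,
                            seed = 1L) {
  format <- match.arg(format)
  assert_scalar_number(seed, "seed", integer = TRUE)
  cfg <- list(
    ref_counts = ref_counts, ref_labels = ref_labels,
    query_counts = query_counts, query_metadata = query_metadata,
    output_dir = output_dir, format = format, qc = qc,
    scale_factor = scale_factor, features_mode = features_mode,
    hvg_k = hvg_k, d = as.integer(d), k = as.integer(k),
    resolution = resolution, l2_strength = l2_strength,
    show_threshold = show_threshold, high_threshold = high_threshold,
    n_perm = as.integer(n_perm), panel_size = as.integer(panel_size),
    seed = as.integer(seed)
  )
  structure(cfg, class = "scw_pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' Configurations round-trip through YAML so runs can be scripted and
#' archived alongside their outputs.
#'
#' @param path YAML file path
#' @return `read_pipeline_config()`: an `scw_pipeline_config`;
#'   `write_pipeline_config()`: `path`, invisibly
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  qc <- do.call(qc_thresholds, obj$qc %||% list())
  obj$qc <- NULL
  do.call(pipeline_config, c(obj, list(qc = qc)))
}

#' @rdname read_pipeline_config
#' @param config an `scw_pipeline_config`
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$qc <- Filter(Negate(is.null), unclass(obj$qc))
  yaml::write_yaml(Filter(Negate(is.null), obj), path)
  invisible(path)
}

validate_pipeline_config <- function(config) {
  if (!inherits(config, "scw_pipeline_config"))
    stopf("'config' must be created by pipeline_config()")
  for (field in c("ref_counts", "ref_labels", "query_counts")) {
    p <- config[[field]]
    if (is.null(p)) stopf("config field '%s' is missing", field)
    if (!file.exists(p) && !dir.exists(p))
      stopf("config field '%s' points to a missing path: %s", field, p)
  }
  if (!is.null(config$query_metadata) &&
      !file.exists(config$query_metadata))
    stopf("config field 'query_metadata' points to a missing path: %s",
          config$query_metadata)
  invisible(config)
}

#' Run the full identity-scoring pipeline
#'
#' Orchestrates the whole analysis in the order QC, normalize, cluster,
#' map, score, wheel, permutation tests:
#' query cells are QC-filtered and both matrices log-library-size
#' normalized on the shared feature space; the query is clustered
#' (PCA, mutual kNN graph, Louvain); a one-vs-rest logistic classifier
#' trained on the reference scores every query cell; clusters are
#' summarized into similarity bands and projected onto the wheel; and
#' each reference type's top-weight gene panel is permutation-tested in
#' the cells assigned to it. All tables are written as TSV into
#' `output_dir`, the fitted classifier as YAML, and a run manifest
#' (config snapshot, package version, per-output MD5 checksums, per-stage
#' timings) as `manifest.yaml`.
#'
#' @param config an [pipeline_config()]
#' @return the manifest, invisibly (a list of class `scw_run_manifest`)
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ref_counts <- stage("read_reference",
                      read_counts(config$ref_counts, config$format))
  ref_tab <- stage("read_reference", read_cell_table(config$ref_labels))
  ref_labels <- stats::setNames(ref_tab[[2L]], ref_tab[[1L]])
  if (!all(rownames(ref_counts) %in% names(ref_labels)))
    stopf("pipeline stage 'read_reference' failed: %d reference cells have no label",
          sum(!rownames(ref_counts) %in% names(ref_labels)))
  ref_labels <- ref_labels[rownames(ref_counts)]
  query_counts <- stage("read_query",
                        read_counts(config$query_counts, config$format))
  metadata <- NULL
  if (!is.null(config$query_metadata))
    metadata <- stage("read_query", read_cell_table(config$query_metadata))
  tick("read")

  groups <- if (!is.null(metadata) && ncol(metadata) >= 2L)
    metadata[[2L]][match(rownames(query_counts), metadata[[1L]])]
  qc_res <- stage("qc", filter_cells(query_counts, config$qc, groups))
  query_counts <- qc_res$counts
  tick("qc")

  ref_norm <- stage("normalize",
                    normalize_log_library(ref_counts, config$scale_factor))
  query_norm <- stage("normalize",
                      normalize_log_library(query_counts,
                                            config$scale_factor))
  features <- stage("normalize", select_features(
    colnames(ref_norm), colnames(query_norm),
    mode = config$features_mode, k = config$hvg_k, ref_norm = ref_norm))
  tick("normalize")

  emb <- stage("cluster", reduce_dimensions(
    query_norm, features, d = min(config$d, nrow(query_norm) - 1L,
                                  length(features)),
    seed = config$seed))
  graph <- stage("cluster", build_knn_graph(emb, k = config$k))
  partition <- stage("cluster", louvain_cluster(
    graph, resolution = config$resolution, seed = config$seed + 1L))
  tick("cluster")

  model <- stage("map", fit_classifier(
    ref_norm, ref_labels, features, l2_strength = config$l2_strength,
    seed = config$seed + 2L))
  probs <- stage("map", predict_probabilities(model, query_norm))
  tick("map")

  similarity <- stage("score", score_clusters(
    probs, partition, high_threshold = config$high_threshold,
    show_threshold = config$show_threshold))
  wheel <- stage("wheel", wheel_coordinates(probs))
  tick("score")

  assigned <- model$types[max.col(probs, ties.method = "first")]
  perm_rows <- list()
  for (type in unique(similarity$assigned_type)) {
    focal <- rownames(probs)[assigned == type]
    comparison <- setdiff(rownames(probs), focal)
    if (!length(focal) || !length(comparison)) next
    panel <- names(sort(model$weights[type, ], decreasing = TRUE)
                   )[seq_len(min(config$panel_size,
                                 ncol(model$weights)))]
    res <- stage("permtest", permutation_test_panel(
      query_norm, panel, focal, comparison, n_perm = config$n_perm,
      seed = config$seed + 3L))
    perm_rows[[type]] <- data.frame(
      reference_type = type, n_focal = length(focal),
      n_comparison = length(comparison), observed = res$observed,
      p_value = res$p_value, n_perm = res$n_perm, seed = res$seed,
      panel = paste(panel, collapse = ","), stringsAsFactors = FALSE)
  }
  perm_table <- if (length(perm_rows))
    do.call(rbind, c(perm_rows, list(make.row.names = FALSE))) else NULL
  tick("permtest")

  out <- function(name) file.path(config$output_dir, name)
  write_cell_table(data.frame(cell_id = names(partition$labels),
                              cluster = partition$labels),
                   out("clusters.tsv"))
  write_cell_table(data.frame(cell_id = rownames(probs),
                              round(probs, 10), check.names = FALSE),
                   out("probabilities.tsv"))
  write_cell_table(as.data.frame(similarity), out("cluster_similarity.tsv"))
  write_cell_table(wheel$vertices, out("wheel_vertices.tsv"))
  write_cell_table(wheel$cells, out("wheel_cells.tsv"))
  if (!is.null(perm_table))
    write_cell_table(perm_table, out("permutation_tests.tsv"))
  write_classifier(model, out("classifier.yaml"))
  qc_rep <- qc_res$report
  write_cell_table(data.frame(
    metric = c("n_cells_in", "n_cells_out", "removed_low_umis",
               "removed_few_genes", "removed_high_mito", "n_genes_in",
               "n_genes_out", "removed_genes_low_support"),
    value = c(qc_rep$n_cells_in, qc_rep$n_cells_out,
              qc_rep$removed_low_umis, qc_rep$removed_few_genes,
              qc_rep$removed_high_mito, qc_rep$n_genes_in,
              qc_rep$n_genes_out, qc_rep$removed_genes_low_support)),
    out("qc_report.tsv"))
  tick("write")

  outputs <- list.files(config$output_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.yaml"]
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("scwheel")),
    config = Filter(Negate(is.null),
                    c(unclass(config)[setdiff(names(config), "qc")],
                      list(qc = Filter(Negate(is.null),
                                       unclass(config$qc))))),
    n_cells_reference = nrow(ref_counts),
    n_cells_query = nrow(query_counts),
    n_features = length(features),
    n_clusters = partition$n_clusters,
    modularity = partition$modularity,
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(sort(outputs))), basename(sort(outputs)))),
    timings_seconds = as.list(timings)
  ), class = "scw_run_manifest")
  yaml::write_yaml(unclass(manifest),
                   file.path(config$output_dir, "manifest.yaml"))
  invisible(manifest)
}
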