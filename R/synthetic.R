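#' Specify a synthetic reference atlas
#'
#' Parameters of the generative model behind [generate_atlas()]. Each cell
#' type is a gene-expression "program": a lognormal baseline propensity per
#' gene, with the type's marker genes up-shifted by `marker_log2fc` log2
#' units. Cells draw a lognormal library size and negative-binomial counts
#' around `library size x normalized program`, the standard overdispersed
#' UMI noise model.
#'
#' Defaults emulate a ventral-midbrain-scale atlas: 10 cell types with 30
#' disjoint marker genes each, a 3 log2-fold marker contrast, and mean
#' library sizes around 10,000 UMIs (inside the 6,753--15,482 range typical
#' of the droplet data this generator stands in for).
#'
#' @param n_types number of cell types (K)
#' @param n_cells_per_type cells generated per type
#' @param n_genes total genes; must be >= markers needed
#' @param n_markers_per_type marker genes private to each type
#' @param marker_log2fc log2 fold-change of markers over baseline (> 0
#'   for signal; 0 gives a null atlas with no type structure)
#' @param marker_overlap number of marker genes each type shares with the
#'   next type (0 = fully disjoint marker sets, the default)
#' @param baseline_mean_log,baseline_sd_log meanlog/sdlog of the lognormal
#'   per-gene baseline expression propensity
#' @param nb_dispersion negative-binomial size (inverse overdispersion)
#' @param libsize_mean_log,libsize_sd_log meanlog/sdlog of the lognormal
#'   per-cell library size
#' @param seed integer seed; the whole atlas is reproducible from it
#' @return an object of class `scw_atlas_spec`
#' @seealso [generate_atlas()], [query_spec()]
#' @export
atlas_spec <- function(n_types = 10L, n_cells_per_type = 200L,
                       n_genes = 2000L, n_markers_per_type = 30L,
                       marker_log2fc = 3, marker_overlap = 0L,
                       baseline_mean_log = 0, baseline_sd_log = 1,
                       nb_dispersion = 2, libsize_mean_log = log(1e4),
                       libsize_sd_log = 0.25, seed = 1L) {
  assert_scalar_number(n_types, "n_types", positive = TRUE, integer = TRUE)
  assert_scalar_number(n_cells_per_type, "n_cells_per_type",
                       positive = TRUE, integer = TRUE)
  assert_scalar_number(n_genes, "n_genes", positive = TRUE, integer = TRUE)
  assert_scalar_number(n_markers_per_type, "n_markers_per_type",
                       positive = TRUE, integer = TRUE)
  assert_scalar_number(marker_log2fc, "marker_log2fc", nonneg = TRUE)
  assert_scalar_number(marker_overlap, "marker_overlap",
                       nonneg = TRUE, integer = TRUE)
  if (marker_overlap >= n_markers_per_type)
    stopf("'marker_overlap' must be smaller than 'n_markers_per_type'")
  assert_scalar_number(baseline_mean_log, "baseline_mean_log")
  assert_scalar_number(baseline_sd_log, "baseline_sd_log", positive = TRUE)
  assert_scalar_number(nb_dispersion, "nb_dispersion", positive = TRUE)
  assert_scalar_number(libsize_mean_log, "libsize_mean_log")
  assert_scalar_number(libsize_sd_log, "libsize_sd_log", nonneg = TRUE)
  assert_scalar_number(seed, "seed", integer = TRUE)
  if (n_types * (n_markers_per_type - marker_overlap) + marker_overlap >
      n_genes)
    stopf("'n_genes' too small: %d types x %d markers exceed %d genes",
          n_types, n_markers_per_type, n_genes)
  structure(list(
    n_types = as.integer(n_types),
    n_cells_per_type = as.integer(n_cells_per_type),
    n_genes = as.integer(n_genes),
    n_markers_per_type = as.integer(n_markers_per_type),
    marker_log2fc = marker_log2fc,
    marker_overlap = as.integer(marker_overlap),
    baseline_mean_log = baseline_mean_log,
    baseline_sd_log = baseline_sd_log,
    nb_dispersion = nb_dispersion,
    libsize_mean_log = libsize_mean_log,
    libsize_sd_log = libsize_sd_log,
    seed = as.integer(seed)
  ), class = "scw_atlas_spec")
}

#' Specify a synthetic query ("differentiation") dataset
#'
#' Query cells are convex mixtures of the atlas's type programs: a one-hot
#' weight row is a pure cell of that type; (0.5, 0.5, 0, ...) is a cell
#' halfway between two identities, emulating transitional progenitors that
#' partially share two programs (not technical doublets, whose counts would
#' add rather than mix).
#'
#' @param n_cells number of query cells (rows of `program_weights`); may
#'   be 0 for an empty query
#' @param program_weights `n_cells x n_types` matrix of mixing weights;
#'   every row must be non-negative and sum to 1 (within 1e-9)
#' @param timepoint_labels,line_labels optional per-cell categorical
#'   metadata carried through to the output
#' @param line_libsize_shift optional named numeric: additive shift of
#'   `libsize_mean_log` per cell line (a per-line depth batch effect)
#' @inheritParams atlas_spec
#' @return an object of class `scw_query_spec`
#' @seealso [generate_query()]
#' @export
query_spec <- function(n_cells, program_weights,
                       nb_dispersion = 2, libsize_mean_log = log(1e4),
                       libsize_sd_log = 0.25, seed = 1L,
                       timepoint_labels = NULL, line_labels = NULL,
                       line_libsize_shift = NULL) {
  assert_scalar_number(n_cells, "n_cells", nonneg = TRUE, integer = TRUE)
  program_weights <- as.matrix(program_weights)
  if (nrow(program_weights) != n_cells)
    stopf("'program_weights' must have one row per cell (%d), got %d",
          n_cells, nrow(program_weights))
  if (n_cells > 0) {
    if (any(!is.finite(program_weights)) || any(program_weights < 0))
      stopf("'program_weights' must be non-negative and finite")
    rs <- rowSums(program_weights)
    if (any(abs(rs - 1) > 1e-9))
      stopf("'program_weights' row(s) %s do not sum to 1",
            paste(utils::head(which(abs(rs - 1) > 1e-9), 5L),
                  collapse = ", "))
  }
  assert_scalar_number(nb_dispersion, "nb_dispersion", positive = TRUE)
  assert_scalar_number(libsize_mean_log, "libsize_mean_log")
  assert_scalar_number(libsize_sd_log, "libsize_sd_log", nonneg = TRUE)
  assert_scalar_number(seed, "seed", integer = TRUE)
  for (nm in c("timepoint_labels", "line_labels")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n_cells)
      stopf("'%s' must have length n_cells (%d)", nm, n_cells)
  }
  structure(list(
    n_cells = as.integer(n_cells),
    program_weights = program_weights,
    nb_dispersion = nb_dispersion,
    libsize_mean_log = libsize_mean_log,
    libsize_sd_log = libsize_sd_log,
    seed = as.integer(seed),
    timepoint_labels = timepoint_labels,
    line_labels = line_labels,
    line_libsize_shift = line_libsize_shift
  ), class = "scw_query_spec")
}

# normalized per-type expression programs (K x G, rows sum to 1) plus the
# per-gene marker-of-type assignment, shared by atlas and query generation
build_programs <- function(spec, baseline) {
  K <- spec$n_types
  G <- spec$n_genes
  step <- spec$n_markers_per_type - spec$marker_overlap
  marker_of_type <- rep(NA_integer_, G)
  programs <- matrix(rep(baseline, each = K), nrow = K)
  for (t in seq_len(K)) {
    idx <- ((t - 1L) * step + 1L):((t - 1L) * step + spec$n_markers_per_type)
    programs[t, idx] <- programs[t, idx] * 2^spec$marker_log2fc
    own <- idx[seq_len(step)]
    marker_of_type[own] <- t  # shared tail markers stay with the earlier type
  }
  programs <- programs / rowSums(programs)
  list(programs = programs, marker_of_type = marker_of_type)
}

nb_counts_matrix <- function(mean_programs, libsizes, dispersion,
                             cell_ids, gene_ids) {
  n <- length(libsizes)
  G <- ncol(mean_programs)
  mu <- mean_programs * libsizes  # rows scaled by per-cell library size
  counts <- matrix(rnbinom(n * G, size = dispersion, mu = as.vector(mu)),
                   nrow = n, ncol = G,
                   dimnames = list(cell_ids, gene_ids))
  as_dgc(counts)
}

#' Generate a labeled synthetic reference atlas
#'
#' Draws `n_types * n_cells_per_type` cells from the generative model in
#' [atlas_spec()]. Counts are negative binomial around
#' `library_size x program`, library sizes lognormal, and each type's
#' markers have expected expression `2^marker_log2fc` times baseline within
#' that type. Fully reproducible from `spec$seed`.
#'
#' @param spec an [atlas_spec()]
#' @return a list of class `scw_atlas` with elements
#'   \describe{
#'     \item{counts}{`dgCMatrix`, cells x genes, integer UMI counts}
#'     \item{labels}{factor of cell-type labels, one per cell}
#'     \item{truth}{ground truth: `dominant_type`, `weights` (one-hot
#'       rows), `marker_of_type`, the normalized `programs` matrix, and
#'       the spec}
#'   }
#' @examples
#' atl <- generate_atlas(atlas_spec(n_types = 3, n_cells_per_type = 20,
#'                                  n_genes = 300, seed = 7))
#' dim(atl$counts)
#' table(atl$labels)
#' @export
generate_atlas <- function(spec) {
  if (!inherits(spec, "scw_atlas_spec"))
    stopf("'spec' must be created by atlas_spec()")
  set.seed(spec$seed)
  K <- spec$n_types
  baseline <- rlnorm(spec$n_genes, spec$baseline_mean_log,
                     spec$baseline_sd_log)
  pr <- build_programs(spec, baseline)
  type_names <- sprintf("type%02d", seq_len(K))
  gene_ids <- sprintf("gene%05d", seq_len(spec$n_genes))
  n <- K * spec$n_cells_per_type
  cell_ids <- sprintf("ref_cell%05d", seq_len(n))
  type_idx <- rep(seq_len(K), each = spec$n_cells_per_type)
  libsizes <- rlnorm(n, spec$libsize_mean_log, spec$libsize_sd_log)
  counts <- nb_counts_matrix(pr$programs[type_idx, , drop = FALSE],
                             libsizes, spec$nb_dispersion,
                             cell_ids, gene_ids)
  weights <- matrix(0, n, K, dimnames = list(cell_ids, type_names))
  weights[cbind(seq_len(n), type_idx)] <- 1
  truth <- list(
    dominant_type = factor(type_names[type_idx], levels = type_names),
    weights = weights,
    marker_of_type = stats::setNames(
      ifelse(is.na(pr$marker_of_type), NA_character_,
             type_names[pr$marker_of_type]), gene_ids),
    programs = `dimnames<-`(pr$programs, list(type_names, gene_ids)),
    spec = spec
  )
  structure(list(
    counts = counts,
    labels = factor(type_names[type_idx], levels = type_names),
    truth = truth
  ), class = "scw_atlas")
}

#' Generate synthetic query cells as mixtures of atlas programs
#'
#' Each query cell's expected expression is the weight-mixture of the
#' atlas's normalized type programs; counts are negative binomial with the
#' query's dispersion and lognormal library sizes. The returned ground
#' truth records the full weight vector and the dominant type (argmax,
#' ties broken by the lowest type index).
#'
#' @param atlas_truth the `truth` element of a [generate_atlas()] result
#' @param spec a [query_spec()]; `program_weights` columns must match the
#'   atlas's type vocabulary in number (and names, if named)
#' @return a list of class `scw_query` with `counts` (cells x genes
#'   `dgCMatrix`), `metadata` (data.frame of cell id, optional time point
#'   and line), and `truth` (`dominant_type`, `weights`)
#' @examples
#' atl <- generate_atlas(atlas_spec(n_types = 3, n_cells_per_type = 20,
#'                                  n_genes = 300, seed = 7))
#' w <- matrix(0, 10, 3); w[, 2] <- 1  # 10 pure cells of type 2
#' q <- generate_query(atl$truth, query_spec(10, w, seed = 8))
#' table(q$truth$dominant_type)
#' @export
generate_query <- function(atlas_truth, spec) {
  if (!inherits(spec, "scw_query_spec"))
    stopf("'spec' must be created by query_spec()")
  programs <- atlas_truth$programs
  K <- nrow(programs)
  type_names <- rownames(programs)
  W <- spec$program_weights
  if (ncol(W) != K)
    stopf("'program_weights' has %d columns but the atlas has %d types",
          ncol(W), K)
  if (!is.null(colnames(W)) && !identical(colnames(W), type_names))
    stopf("'program_weights' column names do not match the atlas types")
  set.seed(spec$seed)
  n <- spec$n_cells
  gene_ids <- colnames(programs)
  cell_ids <- sprintf("query_cell%05d", seq_len(n))
  meanlog <- rep(spec$libsize_mean_log, n)
  if (!is.null(spec$line_libsize_shift) && !is.null(spec$line_labels))
    meanlog <- meanlog +
      unname(spec$line_libsize_shift[as.character(spec$line_labels)])
  if (n == 0L) {
    counts <- as_dgc(matrix(0, 0L, length(gene_ids),
                            dimnames = list(NULL, gene_ids)))
  } else {
    libsizes <- rlnorm(n, meanlog, spec$libsize_sd_log)
    counts <- nb_counts_matrix(W %*% programs, libsizes,
                               spec$nb_dispersion, cell_ids, gene_ids)
  }
  dominant <- if (n) apply(W, 1L, which.max) else integer(0)  # first max wins
  dimnames(W) <- list(cell_ids, type_names)
  metadata <- data.frame(cell_id = cell_ids, stringsAsFactors = FALSE)
  if (!is.null(spec$timepoint_labels))
    metadata$timepoint <- as.character(spec$timepoint_labels)
  if (!is.null(spec$line_labels))
    metadata$line <- as.character(spec$line_labels)
  structure(list(
    counts = counts,
    metadata = metadata,
    truth = list(
      dominant_type = factor(type_names[dominant], levels = type_names),
      weights = W
    )
  ), class = "scw_query")
}

#' Build a program-weight matrix from per-cell type assignments
#'
#' Convenience constructor for [query_spec()]: `pure` rows are one-hot;
#' supplying two types with `mix` in (0, 1) gives every cell the weights
#' `(mix, 1 - mix)` on that pair.
#'
#' @param n_cells number of rows
#' @param types a single type index (pure cells) or a pair (mixed cells)
#' @param n_types total number of atlas types (columns)
#' @param mix weight on the first of the two types when mixing
#' @return an `n_cells x n_types` weight matrix with rows on the simplex
#' @export
program_weights <- function(n_cells, types, n_types, mix = 0.5) {
  W <- matrix(0, n_cells, n_types)
  if (length(types) == 1L) {
    W[, types] <- 1
  } else if (length(types) == 2L) {
    W[, types[1L]] <- mix
    W[, types[2L]] <- 1 - mix
  } else {
    stopf("'types' must have length 1 or 2")
  }
  W
}
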