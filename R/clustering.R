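#' Principal-component embedding of normalized expression
#'
#' Centers the selected feature submatrix and projects it onto its leading
#' principal components. Component signs are fixed deterministically: the
#' loading of largest magnitude in each component is made positive, so the
#' embedding is reproducible across platforms.
#'
#' @param norm cells x genes normalized expression matrix
#' @param features character vector of genes to embed on (see
#'   [select_features()])
#' @param d number of components; must not exceed `min(n_cells,
#'   length(features))` and is additionally capped at `n_cells - 1`, the
#'   rank bound of a centered matrix
#' @param seed integer seed (kept for interface symmetry; PCA itself is
#'   deterministic)
#' @return an object of class `scw_embedding`: list with `coords`
#'   (cells x d), `sdev`, `rotation`, `features`, `method = "pca"`
#' @export
reduce_dimensions <- function(norm, features, d = 50L, seed = 0L) {
  assert_scalar_number(d, "d", positive = TRUE, integer = TRUE)
  assert_scalar_number(seed, "seed", integer = TRUE)
  X <- dense_submatrix(norm, features)
  if (d > min(nrow(X), ncol(X)))
    stopf("d = %d exceeds min(n_cells = %d, n_features = %d)",
          d, nrow(X), ncol(X))
  d <- min(d, nrow(X) - 1L, ncol(X))
  set.seed(seed)
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = d)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    r <- pc$rotation[, j]
    sign(r[which.max(abs(r))])
  }, numeric(1))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2L, flip, `*`)
  rotation <- sweep(pc$rotation, 2L, flip, `*`)
  rownames(coords) <- rownames(X)
  structure(list(
    coords = coords,
    sdev = pc$sdev[seq_len(d)],
    rotation = rotation,
    features = features,
    method = "pca",
    d = d
  ), class = "scw_embedding")
}

#' Mutual k-nearest-neighbor graph over embedded cells
#'
#' Connects every cell to its `k` nearest Euclidean neighbors; the
#' directed kNN relation is symmetrized by union (an undirected edge
#' exists if either cell is among the other's k nearest). Distance ties
#' are broken by the lower cell index. Edge weights are 1.
#'
#' @param emb an [reduce_dimensions()] embedding, or a plain coordinate
#'   matrix (cells x dims)
#' @param k number of neighbors, `1 <= k < n_cells`
#' @param metric only `"euclidean"` is supported
#' @return an undirected `igraph` graph with vertex names = cell ids and
#'   graph attribute `k`
#' @export
build_knn_graph <- function(emb, k = 15L, metric = "euclidean") {
  metric <- match.arg(metric, "euclidean")
  coords <- if (inherits(emb, "scw_embedding")) emb$coords else as.matrix(emb)
  n <- nrow(coords)
  assert_scalar_number(k, "k", positive = TRUE, integer = TRUE)
  if (k >= n)
    stopf("k = %d must be smaller than the number of cells (%d)", k, n)
  dmat <- as.matrix(stats::dist(coords))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dmat[i, ]
    d[i] <- Inf
    nn <- order(d, seq_len(n))[seq_len(k)]  # ties -> lower index first
    edges[[i]] <- cbind(i, nn)
  }
  ep <- do.call(rbind, edges)
  ep <- t(apply(ep, 1L, sort))  # undirected: canonical order, then unique
  ep <- unique(ep)
  g <- igraph::graph_from_edgelist(ep, directed = FALSE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- rownames(coords) %||% as.character(seq_len(n))
  igraph::E(g)$weight <- 1
  g <- igraph::set_graph_attr(g, "k", as.integer(k))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Louvain community detection on a cell graph
#'
#' Greedy modularity optimization (multilevel Louvain) on the kNN graph,
#' the clustering step of a Cytograph-style pipeline. Cluster labels are
#' re-indexed to 0-based contiguous integers in order of first appearance
#' along the cell order, so a fixed seed yields identical labels.
#'
#' @param g an undirected `igraph` graph (see [build_knn_graph()])
#' @param resolution resolution parameter of the modularity objective
#'   (1 = classic modularity; larger values favor more clusters)
#' @param seed integer seed controlling the algorithm's node-order
#'   randomization
#' @return an object of class `scw_partition`: list with `labels`
#'   (named 0-based integer vector), `n_clusters`, `modularity`,
#'   `resolution`, `seed`
#' @export
louvain_cluster <- function(g, resolution = 1, seed = 0L) {
  if (!igraph::is_igraph(g)) stopf("'g' must be an igraph graph")
  if (igraph::vcount(g) == 0L) stopf("graph is empty")
  assert_scalar_number(resolution, "resolution", positive = TRUE)
  assert_scalar_number(seed, "seed", integer = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  relab <- match(memb, unique(memb)) - 1L  # contiguous, first-appearance order
  labels <- stats::setNames(as.integer(relab),
                            igraph::V(g)$name %||% seq_along(relab))
  structure(list(
    labels = labels,
    n_clusters = length(unique(relab)),
    modularity = igraph::modularity(g, memb, resolution = resolution),
    resolution = resolution,
    seed = as.integer(seed)
  ), class = "scw_partition")
}

#' @export
print.scw_partition <- function(x, ...) {
  cat(sprintf("Louvain partition: %d cells, %d clusters, modularity %.4f (resolution %g)\n",
              length(x$labels), x$n_clusters, x$modularity, x$resolution))
  invisible(x)
}

#' Cluster composition by a categorical covariate
#'
#' Per-cluster counts and row-normalized proportions of a per-cell
#' categorical such as cell line or time point — the balance check that
#' both lines contribute similar proportions to every cluster.
#'
#' @param partition an [louvain_cluster()] partition (or a per-cell label
#'   vector)
#' @param metadata per-cell categorical, aligned with the cells
#' @return list with `counts` and `proportions` (clusters x categories
#'   matrices) and `max_imbalance`, the largest absolute deviation of a
#'   proportion from the category's overall share
#' @export
report_composition <- function(partition, metadata) {
  labels <- if (inherits(partition, "scw_partition"))
    partition$labels else partition
  if (length(metadata) != length(labels))
    stopf("'metadata' must have one entry per cell (%d), got %d",
          length(labels), length(metadata))
  tab <- table(cluster = labels, category = factor(metadata))
  counts <- unclass(as.matrix(tab))
  props <- counts / rowSums(counts)
  overall <- colSums(counts) / sum(counts)
  list(counts = counts, proportions = props,
       max_imbalance = max(abs(sweep(props, 2L, overall, `-`))))
}
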