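test_that("PCA matches a brute-force eigendecomposition on a toy matrix", {
  set.seed(3)
  X <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("c", 1:5), paste0("g", 1:4)))
  emb <- reduce_dimensions(X, colnames(X), d = 3, seed = 0)
  eig <- eigen(stats::cov(X))
  expect_equal(emb$sdev^2, eig$values[1:3], tolerance = 1e-9)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  scores <- Xc %*% eig$vectors[, 1:3]
  # components agree up to sign; the package fixes signs deterministically
  for (j in 1:3)
    expect_equal(abs(unname(emb$coords[, j])), abs(unname(scores[, j])),
                 tolerance = 1e-9)
  r <- emb$rotation
  expect_true(all(vapply(1:3, function(j)
    r[which.max(abs(r[, j])), j] > 0, logical(1))))
})

test_that("rank-1 data leaves no variance for the second component", {
  t_param <- seq(0, 1, length.out = 10)
  X <- cbind(t_param, 2 * t_param, -t_param)
  rownames(X) <- paste0("c", 1:10); colnames(X) <- paste0("g", 1:3)
  emb <- reduce_dimensions(X, colnames(X), d = 2, seed = 0)
  expect_lt(emb$sdev[2]^2, 1e-9)
})

test_that("orthogonal rotation of the data preserves the PCA spectrum", {
  set.seed(4)
  X <- matrix(rnorm(60), 15, 4,
              dimnames = list(paste0("c", 1:15), paste0("g", 1:4)))
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  XQ <- X %*% Q
  dimnames(XQ) <- dimnames(X)
  e1 <- reduce_dimensions(X, colnames(X), d = 4, seed = 0)
  e2 <- reduce_dimensions(XQ, colnames(X), d = 4, seed = 0)
  expect_equal(e1$sdev, e2$sdev, tolerance = 1e-9)
})

test_that("d larger than the data is rejected", {
  X <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  expect_error(reduce_dimensions(X, colnames(X), d = 5), "exceeds")
})

test_that("kNN graph on collinear points follows hand geometry", {
  X <- cbind(c(0, 1, 2, 3), 0)
  rownames(X) <- paste0("c", 1:4)
  g <- build_knn_graph(X, k = 1)
  edges <- igraph::as_edgelist(g)
  edges <- t(apply(edges, 1, sort))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  # c2's tie between c1 and c3 breaks to the lower index; c3's to c2,
  # which mutualizes into the middle edge
  expect_identical(edges, rbind(c("c1", "c2"), c("c2", "c3"),
                                c("c3", "c4")))
})

test_that("k = n - 1 saturates to the complete graph", {
  set.seed(5)
  X <- matrix(rnorm(12), 6, 2)
  g <- build_knn_graph(X, k = 5)
  expect_equal(igraph::ecount(g), 15)
  expect_error(build_knn_graph(X, k = 6), "smaller")
})

test_that("duplicated points are each other's first neighbors", {
  X <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  rownames(X) <- paste0("c", 1:4)
  g <- build_knn_graph(X, k = 1)
  expect_true(igraph::are_adjacent(g, "c1", "c2"))
  expect_true(igraph::are_adjacent(g, "c3", "c4"))
  expect_equal(igraph::ecount(g), 2)
})

test_that("two disjoint 3-cliques split into 2 clusters at modularity 1/2", {
  g <- igraph::graph_from_edgelist(rbind(
    c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)),
    directed = FALSE)
  part <- louvain_cluster(g, resolution = 1, seed = 0)
  expect_identical(part$n_clusters, 2L)
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  expect_identical(unname(part$labels), c(0L, 0L, 0L, 1L, 1L, 1L))
})

test_that("a complete graph collapses to one cluster", {
  g <- igraph::make_full_graph(8)
  part <- louvain_cluster(g, resolution = 1, seed = 0)
  expect_identical(part$n_clusters, 1L)
})

test_that("clustering is deterministic given the seed", {
  atl <- small_atlas(n_types = 3, n_cells_per_type = 50, seed = 81)
  norm <- normalize_log_library(atl$counts)
  emb <- reduce_dimensions(norm, colnames(norm), d = 10, seed = 1)
  g <- build_knn_graph(emb, k = 10)
  p1 <- louvain_cluster(g, seed = 7)
  p2 <- louvain_cluster(g, seed = 7)
  expect_identical(p1$labels, p2$labels)
})

test_that("partitions survive cell permutation up to label renaming", {
  atl <- small_atlas(n_types = 3, n_cells_per_type = 40, seed = 82)
  norm <- normalize_log_library(atl$counts)
  emb <- reduce_dimensions(norm, colnames(norm), d = 10, seed = 1)
  p1 <- louvain_cluster(build_knn_graph(emb, k = 10), seed = 3)
  set.seed(9)
  perm <- sample(nrow(norm))
  p2 <- louvain_cluster(build_knn_graph(emb$coords[perm, ], k = 10),
                        seed = 3)
  expect_equal(mclust::adjustedRandIndex(
    p1$labels[names(p2$labels)], p2$labels), 1)
})

test_that("well-separated synthetic types are recovered (ARI >= 0.9)", {
  atl <- generate_atlas(atlas_spec(n_types = 3, n_cells_per_type = 100,
                                   n_genes = 600, n_markers_per_type = 20,
                                   marker_log2fc = 3, seed = 91))
  norm <- normalize_log_library(atl$counts)
  emb <- reduce_dimensions(norm, colnames(norm), d = 20, seed = 1)
  part <- louvain_cluster(build_knn_graph(emb, k = 15), seed = 2)
  ari <- mclust::adjustedRandIndex(part$labels, atl$labels)
  expect_gte(ari, 0.9)
  expect_gte(part$modularity, 0)
})

test_that("composition tables report counts, proportions, imbalance", {
  labels <- rep(c(0L, 1L), each = 10)
  lines <- rep(c("A", "B"), 10)
  comp <- report_composition(labels, lines)
  expect_true(all(comp$proportions == 0.5))
  expect_equal(comp$max_imbalance, 0)

  comp2 <- report_composition(rep(0L, 10), rep("A", 10))
  expect_identical(unname(comp2$proportions[1, 1]), 1)
  expect_error(report_composition(labels, lines[1:5]), "per cell")
})

test_that("a pure depth shift between lines does not split clusters", {
  atl <- generate_atlas(atlas_spec(n_types = 2, n_cells_per_type = 100,
                                   n_genes = 400, n_markers_per_type = 20,
                                   seed = 93))
  lines <- rep(c("H9", "HS980"), 200)
  q <- generate_query(atl$truth, query_spec(
    400, rbind(program_weights(200, 1, 2), program_weights(200, 2, 2)),
    line_labels = lines, line_libsize_shift = c(H9 = 0, HS980 = 0.3),
    seed = 94))
  norm <- normalize_log_library(q$counts)
  emb <- reduce_dimensions(norm, colnames(norm), d = 10, seed = 1)
  part <- louvain_cluster(build_knn_graph(emb, k = 15), seed = 2)
  comp <- report_composition(part, lines)
  big <- rowSums(comp$counts) >= 100
  expect_lt(max(abs(comp$proportions[big, "H9"] - 0.5)), 0.2)
})
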