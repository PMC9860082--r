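test_that("a separable 1-D toy problem puts the boundary at zero", {
  X <- matrix(c(rep(-1, 20), rep(1, 20)), ncol = 1,
              dimnames = list(paste0("c", 1:40), "g1"))
  labels <- rep(c("neg", "pos"), each = 20)
  model <- fit_classifier(X, labels, "g1", l2_strength = 1, seed = 0)
  p <- predict_probabilities(model, X)
  expect_true(all(max.col(p) == c(rep(1, 20), rep(2, 20))))
  # symmetric classes: the decision boundary sits at x = 0
  mid <- predict_probabilities(model, matrix(0, 1, 1,
                                             dimnames = list("m", "g1")))
  expect_equal(unname(mid[1, 1]), 0.5, tolerance = 1e-6)
})

test_that("training on permuted labels yields prior-level probabilities", {
  atl <- generate_atlas(atlas_spec(n_types = 3, n_cells_per_type = 100,
                                   n_genes = 300, n_markers_per_type = 15,
                                   seed = 101))
  norm <- normalize_log_library(atl$counts)
  feats <- select_features(colnames(norm), colnames(norm))
  set.seed(102)
  shuffled <- sample(as.character(atl$labels))
  model <- fit_classifier(norm, shuffled, feats, seed = 0)
  q <- generate_query(atl$truth, query_spec(
    300, program_weights(300, 1, 3), seed = 103))
  p <- predict_probabilities(model, normalize_log_library(q$counts))
  priors <- rep(1 / 3, 3)
  expect_true(all(abs(colMeans(p) - priors) < 0.1))
})

test_that("held-out accuracy is high on a well-separated 10-type atlas", {
  atl <- generate_atlas(atlas_spec(n_types = 10, n_cells_per_type = 60,
                                   n_genes = 1000, n_markers_per_type = 20,
                                   marker_log2fc = 3, seed = 111))
  norm <- normalize_log_library(atl$counts)
  feats <- select_features(colnames(norm), colnames(norm))
  set.seed(112)
  test_idx <- sample(nrow(norm), round(0.2 * nrow(norm)))
  model <- fit_classifier(norm[-test_idx, ], atl$labels[-test_idx],
                          feats, seed = 0)
  p <- predict_probabilities(model, norm[test_idx, ])
  acc <- mean(model$types[max.col(p)] ==
                as.character(atl$labels[test_idx]))
  expect_gte(acc, 0.95)
})

test_that("classifier rejects degenerate inputs by name", {
  X <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("c", 1:10), paste0("g", 1:4)))
  expect_error(fit_classifier(X, rep("a", 10), colnames(X)), "2 reference")
  expect_error(fit_classifier(X, c("a", rep("b", 9)), colnames(X)),
               "fewer than 2 cells: a")
  X[1, 1] <- NA
  expect_error(fit_classifier(X, rep(c("a", "b"), 5), colnames(X)),
               "non-finite")
})

test_that("predicted probabilities equal a hand-coded sigmoid evaluation", {
  model <- structure(list(
    weights = matrix(c(1, -0.5, -1, 2), 2, 2, byrow = TRUE,
                     dimnames = list(c("t1", "t2"), c("g1", "g2"))),
    intercepts = c(t1 = 0.25, t2 = -0.1),
    types = c("t1", "t2"), features = c("g1", "g2"),
    l2_strength = 1, scheme = "ovr", normalization = "log_library"
  ), class = "scw_classifier")
  X <- matrix(c(0.3, 1.2, 0, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("g1", "g2")))
  p <- predict_probabilities(model, X)
  for (i in 1:2) {
    s1 <- 1 / (1 + exp(-(0.25 + 1 * X[i, 1] - 0.5 * X[i, 2])))
    s2 <- 1 / (1 + exp(-(-0.1 - 1 * X[i, 1] + 2 * X[i, 2])))
    expect_equal(unname(p[i, ]), c(s1, s2) / (s1 + s2), tolerance = 1e-9)
  }
})

test_that("probability rows always lie on the simplex", {
  atl <- small_atlas(seed = 121)
  norm <- normalize_log_library(atl$counts)
  feats <- select_features(colnames(norm), colnames(norm))
  model <- fit_classifier(norm, atl$labels, feats, seed = 0)
  p <- predict_probabilities(model, norm)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-9)

  # an all-zero cell under a zero-weight model scores uniformly
  zero_model <- model
  zero_model$weights[] <- 0
  zero_model$intercepts[] <- 0
  z <- matrix(0, 1, ncol(norm), dimnames = list("z", colnames(norm)))
  expect_equal(unname(predict_probabilities(zero_model, z)[1, ]),
               rep(0.25, 4), tolerance = 1e-12)

  # empty query: empty matrix, typed columns
  e <- predict_probabilities(model, norm[0, , drop = FALSE])
  expect_identical(dim(e), c(0L, 4L))
})

test_that("missing features are reported, not silently imputed", {
  atl <- small_atlas(n_types = 2, n_cells_per_type = 20, seed = 122)
  norm <- normalize_log_library(atl$counts)
  model <- fit_classifier(norm, atl$labels, colnames(norm), seed = 0)
  expect_error(predict_probabilities(model, norm[, -1, drop = FALSE]),
               "missing")
})

test_that("cluster similarity bands follow the 0.5 / 0.8 convention", {
  p <- rbind(
    matrix(rep(c(1, 0, 0), 5), 5, 3, byrow = TRUE),     # one-hot on t1
    matrix(rep(c(0.85, 0.10, 0.05), 5), 5, 3, byrow = TRUE),
    matrix(rep(c(0.60, 0.25, 0.15), 5), 5, 3, byrow = TRUE),
    matrix(rep(c(0.40, 0.35, 0.25), 5), 5, 3, byrow = TRUE))
  colnames(p) <- c("t1", "t2", "t3")
  rownames(p) <- paste0("c", 1:20)
  cs <- score_clusters(p, rep(0:3, each = 5))
  expect_identical(as.character(cs$band),
                   c("high", "high", "moderate", "below"))
  expect_equal(cs$similarity, c(1, 0.85, 0.60, 0.40), tolerance = 1e-12)
  expect_identical(cs$assigned_type, rep("t1", 4))
  expect_equal(cs$frac_high, c(1, 1, 0, 0))

  # boundary scores land in exactly one band
  pb <- matrix(rep(c(0.8, 0.15, 0.05), 4), 4, 3, byrow = TRUE,
               dimnames = list(paste0("b", 1:4), c("t1", "t2", "t3")))
  expect_identical(as.character(score_clusters(pb, rep(0, 4))$band),
                   "high")
})

test_that("wheel geometry maps certainty to vertices, confusion to origin", {
  K <- 5
  types <- paste0("t", 1:K)
  p <- diag(K)
  dimnames(p) <- list(paste0("c", 1:K), types)
  wl <- wheel_coordinates(p)
  expect_equal(wl$cells$x, wl$vertices$x, tolerance = 1e-12)
  expect_equal(wl$cells$y, wl$vertices$y, tolerance = 1e-12)
  expect_equal(wl$vertices$x[1], 1)  # vertex 0 at angle 0

  u <- matrix(1 / K, 1, K, dimnames = list("u", types))
  wu <- wheel_coordinates(u)
  expect_lt(max(abs(c(wu$cells$x, wu$cells$y))), 1e-12)

  # a 50/50 cell on adjacent vertices lands on the chord midpoint
  mix <- matrix(c(0.5, 0.5, 0, 0, 0), 1, K, dimnames = list("m", types))
  wm <- wheel_coordinates(mix)
  expect_equal(wm$cells$x, (wl$vertices$x[1] + wl$vertices$x[2]) / 2,
               tolerance = 1e-12)
  expect_equal(wm$cells$y, (wl$vertices$y[1] + wl$vertices$y[2]) / 2,
               tolerance = 1e-12)

  expect_error(wheel_coordinates(p, vertex_order = c("t1", "t2")),
               "permutation")

  # all points stay inside the polygon: the max radius of any convex
  # combination is the vertex radius
  set.seed(131)
  rand <- matrix(stats::rexp(100 * K), 100, K)
  rand <- rand / rowSums(rand)
  colnames(rand) <- types
  wr <- wheel_coordinates(rand)
  expect_true(all(sqrt(wr$cells$x^2 + wr$cells$y^2) <= 1 + 1e-12))
})

test_that("a trained classifier round-trips through its text file", {
  atl <- small_atlas(n_types = 2, n_cells_per_type = 20,
                     n_genes = 100, seed = 141)
  norm <- normalize_log_library(atl$counts)
  model <- fit_classifier(norm, atl$labels, colnames(norm), seed = 0)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_classifier(model, path)
  back <- read_classifier(path)
  expect_equal(back$weights, model$weights, tolerance = 1e-12)
  expect_equal(unname(back$intercepts), unname(model$intercepts),
               tolerance = 1e-12)
  expect_identical(back$types, model$types)
  p1 <- predict_probabilities(model, norm)
  p2 <- predict_probabilities(back, norm)
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("accuracy never degrades as the marker contrast grows", {
  accs <- vapply(c(1, 2, 3), function(fc) {
    atl <- generate_atlas(atlas_spec(n_types = 4, n_cells_per_type = 50,
                                     n_genes = 400,
                                     n_markers_per_type = 15,
                                     marker_log2fc = fc, seed = 151))
    norm <- normalize_log_library(atl$counts)
    set.seed(152)
    test_idx <- sample(nrow(norm), 40)
    model <- fit_classifier(norm[-test_idx, ], atl$labels[-test_idx],
                            colnames(norm), seed = 0)
    p <- predict_probabilities(model, norm[test_idx, ])
    mean(model$types[max.col(p)] == as.character(atl$labels[test_idx]))
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})
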