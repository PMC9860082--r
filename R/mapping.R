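#' Train a one-vs-rest logistic-regression cell-type classifier
#'
#' Fits one L2-regularized binary logistic regression per reference type
#' (that type against all others) on the normalized expression of the
#' selected features. This is the label-transfer model used to score how
#' similar query cells are to each endogenous reference type. Each binary
#' problem minimizes
#' \deqn{\sum_i \log(1 + e^{\eta_i}) - \sum_{i: y_i = 1} \eta_i +
#'       \frac{\lambda}{2}\lVert w \rVert^2, \quad \eta_i = b + x_i^T w,}
#' by L-BFGS; the intercept is not penalized. Convergence is declared when
#' the per-cell-averaged gradient falls below `tol` (otherwise a warning
#' is issued after `max_iter` iterations).
#'
#' @param ref_norm cells x genes normalized reference expression (see
#'   [normalize_log_library()]); no feature scaling is applied
#' @param labels per-cell reference type labels (factor or character)
#' @param features genes to train on (see [select_features()])
#' @param l2_strength ridge penalty `lambda` (> 0); default 1
#' @param seed integer seed (the fit is deterministic from a zero start;
#'   kept for interface symmetry)
#' @param max_iter L-BFGS iteration cap per binary problem
#' @param tol convergence tolerance on the infinity norm of the averaged
#'   gradient
#' @return an object of class `scw_classifier`: list with `weights`
#'   (types x features), `intercepts`, `types`, `features`,
#'   `l2_strength`, `scheme = "ovr"`, `normalization = "log_library"`
#' @seealso [predict_probabilities()]
#' @export
fit_classifier <- function(ref_norm, labels, features, l2_strength = 1,
                           seed = 0L, max_iter = 500L, tol = 1e-6) {
  assert_scalar_number(l2_strength, "l2_strength", positive = TRUE)
  assert_scalar_number(seed, "seed", integer = TRUE)
  labels <- factor(labels)
  X <- dense_submatrix(ref_norm, features)
  if (any(!is.finite(X)))
    stopf("'ref_norm' contains non-finite values")
  if (nrow(X) != length(labels))
    stopf("'labels' must have one entry per cell")
  types <- levels(labels)
  if (length(types) < 2L)
    stopf("at least 2 reference types are required, got %d", length(types))
  counts_per_type <- table(labels)
  small <- names(counts_per_type)[counts_per_type < 2L]
  if (length(small))
    stopf("type(s) with fewer than 2 cells: %s",
          paste(small, collapse = ", "))
  set.seed(seed)
  n <- nrow(X)
  p <- ncol(X)
  W <- matrix(0, length(types), p, dimnames = list(types, features))
  b <- stats::setNames(numeric(length(types)), types)
  for (t in seq_along(types)) {
    y <- as.numeric(labels == types[t])
    fit <- fit_binary_ridge_logistic(X, y, l2_strength, max_iter)
    gnorm <- max(abs(fit$grad)) / n
    if (gnorm > tol)
      warnf("classifier for type '%s' stopped at averaged gradient norm %.2e > %.0e after %d iterations",
            types[t], gnorm, tol, max_iter)
    b[t] <- fit$theta[1L]
    W[t, ] <- fit$theta[-1L]
  }
  structure(list(
    weights = W, intercepts = b, types = types, features = features,
    l2_strength = l2_strength, scheme = "ovr",
    normalization = "log_library"
  ), class = "scw_classifier")
}

# one penalized binary logistic fit; theta = c(intercept, weights).
# L-BFGS does the bulk of the work; damped Newton steps polish the
# solution to the gradient tolerance when the line search stalls early.
fit_binary_ridge_logistic <- function(X, y, lambda, max_iter,
                                      grad_tol = 1e-6) {
  n <- nrow(X)
  negloglik <- function(theta) {
    eta <- theta[1L] + drop(X %*% theta[-1L])
    # log(1 + e^eta) - y*eta, stable for large |eta|
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
      0.5 * lambda * sum(theta[-1L]^2)
  }
  gradient <- function(theta) {
    eta <- theta[1L] + drop(X %*% theta[-1L])
    r <- plogis(eta) - y
    c(sum(r), drop(crossprod(X, r)) + lambda * theta[-1L])
  }
  fit <- optim(rep(0, ncol(X) + 1L), negloglik, gradient,
               method = "L-BFGS-B",
               control = list(maxit = max_iter, factr = 10, pgtol = 0))
  theta <- fit$par
  value <- fit$value
  for (step in seq_len(5L)) {
    g <- gradient(theta)
    if (max(abs(g)) / n <= grad_tol) break
    eta <- theta[1L] + drop(X %*% theta[-1L])
    s <- plogis(eta)
    w <- pmax(s * (1 - s), 1e-10)
    X1 <- cbind(1, X)
    H <- crossprod(X1 * w, X1)
    diag(H) <- diag(H) + c(1e-10, rep(lambda, ncol(X)))
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta)) break
    stepsize <- 1
    repeat {
      cand <- theta - stepsize * delta
      v <- negloglik(cand)
      if (v <= value || stepsize < 1e-4) break
      stepsize <- stepsize / 2
    }
    if (v > value) break
    theta <- cand
    value <- v
  }
  list(theta = theta, grad = gradient(theta), value = value)
}

#' @export
print.scw_classifier <- function(x, ...) {
  cat(sprintf("one-vs-rest logistic classifier: %d types, %d features, lambda = %g\n",
              length(x$types), length(x$features), x$l2_strength))
  invisible(x)
}

#' Score query cells against the reference types
#'
#' Evaluates each type's one-vs-rest sigmoid on the query cells and
#' renormalizes the scores to sum to 1 per cell, so every row is a point
#' on the probability simplex over reference types. The entries are the
#' per-cell "similarity" probabilities summarized downstream by
#' [score_clusters()] and visualized by [wheel_coordinates()].
#'
#' @param model an [fit_classifier()] model
#' @param query_norm cells x genes normalized query expression; must
#'   contain every model feature (an error lists any that are missing —
#'   re-run [select_features()] on the pair if so)
#' @return numeric matrix cells x types; rows sum to 1 (within 1e-9)
#' @export
predict_probabilities <- function(model, query_norm) {
  if (!inherits(model, "scw_classifier"))
    stopf("'model' must be created by fit_classifier()")
  if (nrow(query_norm) == 0L)
    return(matrix(numeric(0), 0L, length(model$types),
                  dimnames = list(NULL, model$types)))
  X <- dense_submatrix(query_norm, model$features)
  eta <- sweep(X %*% t(model$weights), 2L, model$intercepts, `+`)
  s <- plogis(eta)
  probs <- s / rowSums(s)
  dimnames(probs) <- list(rownames(query_norm), model$types)
  probs
}

#' Summarize per-cluster similarity to reference types
#'
#' Averages the per-cell probabilities within each cluster, assigns every
#' cluster the type with the highest mean probability (ties broken by the
#' lower type index), and bands the similarity score the way the wheel
#' figures report it: below 0.5 ("below", usually hidden), 0.5--0.79
#' ("moderate"), 0.8--1.0 ("high"). The half-open implementation
#' `[0.5, 0.8)` / `[0.8, 1]` gives every score exactly one band. Also
#' reported is the fraction of member cells whose own probability for the
#' assigned type reaches `high_threshold` — the per-cluster "fraction of
#' cells highly resembling" the endogenous type.
#'
#' @param probs cells x types probability matrix from
#'   [predict_probabilities()]
#' @param partition an [louvain_cluster()] partition or per-cell cluster
#'   label vector aligned with the rows of `probs`
#' @param high_threshold lower edge of the "high" band (default 0.8)
#' @param show_threshold lower edge of the "moderate" band; clusters below
#'   it are flagged `"below"` (default 0.5)
#' @return a data.frame of class `scw_cluster_similarity` with one row
#'   per cluster: `cluster`, `n_cells`, `assigned_type`, `similarity`,
#'   `band`, `frac_high`; the full clusters x types mean-probability
#'   matrix is attached as attribute `"mean_probs"`
#' @export
score_clusters <- function(probs, partition, high_threshold = 0.8,
                           show_threshold = 0.5) {
  labels <- if (inherits(partition, "scw_partition"))
    partition$labels else partition
  if (length(labels) != nrow(probs))
    stopf("partition has %d cells but 'probs' has %d rows",
          length(labels), nrow(probs))
  if (show_threshold > high_threshold)
    stopf("'show_threshold' must not exceed 'high_threshold'")
  clusters <- sort(unique(labels))
  types <- colnames(probs)
  mean_probs <- t(vapply(clusters, function(cl)
    colMeans(probs[labels == cl, , drop = FALSE]),
    numeric(ncol(probs))))
  rownames(mean_probs) <- as.character(clusters)
  assigned <- max.col(mean_probs, ties.method = "first")
  similarity <- mean_probs[cbind(seq_along(clusters), assigned)]
  band <- ifelse(similarity >= high_threshold, "high",
                 ifelse(similarity >= show_threshold, "moderate", "below"))
  frac_high <- vapply(seq_along(clusters), function(i) {
    p <- probs[labels == clusters[i], assigned[i]]
    mean(p >= high_threshold)
  }, numeric(1))
  out <- data.frame(
    cluster = clusters,
    n_cells = as.integer(table(factor(labels, levels = clusters))),
    assigned_type = types[assigned],
    similarity = similarity,
    band = factor(band, levels = c("below", "moderate", "high")),
    frac_high = frac_high,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "mean_probs") <- mean_probs
  attr(out, "thresholds") <- c(show = show_threshold, high = high_threshold)
  class(out) <- c("scw_cluster_similarity", "data.frame")
  out
}

#' Wheel (probability-simplex polygon) coordinates
#'
#' Places the K reference types at equal angles on the unit circle and
#' maps every cell to the probability-weighted average of the vertex
#' coordinates. A cell certain of one identity sits exactly on that
#' vertex; a maximally uncertain cell sits at the origin; mixtures lie on
#' the chord between their contributing vertices. All points stay inside
#' the polygon's convex hull because rows are convex weights.
#'
#' @param probs cells x types probability matrix
#' @param vertex_order permutation of the type vocabulary giving the
#'   vertex arrangement; defaults to column order. Vertex `j` (0-based
#'   position in this order) sits at angle `2*pi*j/K`.
#' @return an object of class `scw_wheel`: list with `vertices`
#'   (data.frame type, x, y), `cells` (data.frame cell_id, x, y) and
#'   `vertex_order`
#' @export
wheel_coordinates <- function(probs, vertex_order = colnames(probs)) {
  types <- colnames(probs)
  if (is.null(types)) stopf("'probs' must have type column names")
  if (!setequal(vertex_order, types) ||
      length(vertex_order) != length(types))
    stopf("'vertex_order' must be a permutation of the type vocabulary")
  K <- length(types)
  theta <- 2 * pi * (seq_len(K) - 1L) / K
  V <- cbind(x = cos(theta), y = sin(theta))
  P <- probs[, vertex_order, drop = FALSE]
  XY <- P %*% V
  structure(list(
    vertices = data.frame(type = vertex_order, x = V[, 1L], y = V[, 2L],
                          stringsAsFactors = FALSE),
    cells = data.frame(cell_id = rownames(probs) %||%
                         as.character(seq_len(nrow(probs))),
                       x = XY[, 1L], y = XY[, 2L],
                       stringsAsFactors = FALSE),
    vertex_order = vertex_order
  ), class = "scw_wheel")
}

#' Plot a wheel layout
#'
#' @param x an [wheel_coordinates()] object
#' @param col point color(s), recycled over cells
#' @param ... further arguments passed to [graphics::points()]
#' @return `x`, invisibly
#' @export
plot.scw_wheel <- function(x, col = grDevices::adjustcolor("steelblue", 0.5),
                           ...) {
  v <- x$vertices
  graphics::plot(NA, xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  graphics::polygon(v$x, v$y, border = "grey40")
  graphics::points(x$cells$x, x$cells$y, pch = 16, col = col, ...)
  graphics::text(1.12 * v$x, 1.12 * v$y, v$type, cex = 0.8)
  invisible(x)
}

#' Serialize / restore a fitted classifier as structured text
#'
#' The model (weights, intercepts, features, vocabulary, hyperparameters)
#' round-trips through a YAML file, so a trained reference mapping can be
#' reused without refitting.
#'
#' @param model an [fit_classifier()] model
#' @param path file path to write to / read from
#' @return `write_classifier()` returns `path` invisibly;
#'   `read_classifier()` returns the restored `scw_classifier`
#' @export
write_classifier <- function(model, path) {
  if (!inherits(model, "scw_classifier"))
    stopf("'model' must be created by fit_classifier()")
  yaml::write_yaml(list(
    scheme = model$scheme,
    normalization = model$normalization,
    l2_strength = model$l2_strength,
    types = model$types,
    features = model$features,
    intercepts = as.numeric(model$intercepts),
    weights = lapply(seq_along(model$types),
                     function(i) as.numeric(model$weights[i, ]))
  ), path, precision = 17L)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- yaml::read_yaml(path)
  W <- do.call(rbind, lapply(obj$weights, as.numeric))
  dimnames(W) <- list(obj$types, obj$features)
  structure(list(
    weights = W,
    intercepts = stats::setNames(as.numeric(obj$intercepts), obj$types),
    types = obj$types, features = obj$features,
    l2_strength = obj$l2_strength, scheme = obj$scheme,
    normalization = obj$normalization
  ), class = "scw_classifier")
}
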