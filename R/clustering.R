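#' Mini-batch k-means
#'
#' Lightweight seeded mini-batch k-means used to form meta-cells before
#' community detection on large datasets. Centers are initialized from a
#' random sample of points and updated with per-center learning rates
#' 1/count (the standard streaming update).
#'
#' @param x numeric matrix (points in rows).
#' @param k number of centers.
#' @param batch_size points per mini-batch.
#' @param iters number of mini-batch updates.
#' @param rng_seed integer seed.
#' @return list with `centers` (k x ncol(x)) and `assignment` (length
#'   nrow(x), values in 1..k, every point assigned to its nearest center).
#' @keywords internal
minibatch_kmeans <- function(x, k, batch_size = 256L, iters = 100L,
                             rng_seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- min(k, n)
  set.seed(rng_seed)
  centers <- x[sample.int(n, k), , drop = FALSE]
  counts <- rep(0, k)
  nearest <- function(pts, ctr) {
    d2 <- outer(rowSums(pts^2), rowSums(ctr^2), "+") - 2 * tcrossprod(pts, ctr)
    max.col(-d2, ties.method = "first")
  }
  for (it in seq_len(iters)) {
    b <- x[sample.int(n, min(batch_size, n)), , drop = FALSE]
    a <- nearest(b, centers)
    for (j in unique(a)) {
      rows <- which(a == j)
      for (r in rows) {
        counts[j] <- counts[j] + 1
        eta <- 1 / counts[j]
        centers[j, ] <- (1 - eta) * centers[j, ] + eta * b[r, ]
      }
    }
  }
  assignment <- nearest(x, centers)
  list(centers = centers, assignment = assignment)
}

# kNN graph (undirected union of directed kNN edges) + Leiden communities
leiden_on_knn <- function(z, knn_k = 15L, resolution = 1.0, rng_seed = 1L) {
  n <- nrow(z)
  knn_k <- min(knn_k, n - 1L)
  nn <- knn_index(z, knn_k)
  edges <- cbind(rep(seq_len(n), knn_k), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(rng_seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 3L)
  igraph::membership(cl)
}

#' Cluster the augmented cells
#'
#' Rows are expected centered/scaled (see [log_standardize()] with
#' `axis = "rows"`). For `nrow(m) <= small_threshold` the data are projected
#' onto `n_pcs` principal components, a k-nearest-neighbour graph is built
#' and Leiden community detection (modularity objective) is run directly.
#' Larger datasets are first reduced to meta-cells with mini-batch k-means
#' (`k = ceiling(meta_fraction * rows)`); Leiden then runs on the
#' neighbourhood graph of the meta-cell centroids and every cell inherits
#' its meta-cell's community.
#'
#' @param m numeric matrix of (row-standardized) expression values.
#' @param small_threshold row count at or below which Leiden runs on cells
#'   directly (default 1000).
#' @param meta_fraction meta-cell count as a fraction of rows (default 0.10).
#' @param n_pcs principal components for the embedding (default 30).
#' @param knn_k neighbourhood-graph degree (default 15).
#' @param resolution Leiden resolution (default 1.0).
#' @param rng_seed integer seed.
#' @return list of class `cluster_labels`: `assignments` (integer vector,
#'   contiguous labels 0..n_clusters-1) and `n_clusters`.
#' @export
cluster_cells <- function(m, small_threshold = 1000L, meta_fraction = 0.10,
                          n_pcs = 30L, knn_k = 15L, resolution = 1.0,
                          rng_seed = 1L) {
  m <- as.matrix(m)
  n <- nrow(m)
  z <- pca_project(m, n_pcs)
  if (n <= small_threshold) {
    memb <- leiden_on_knn(z, knn_k, resolution, rng_seed)
  } else {
    k_meta <- as.integer(ceiling(meta_fraction * n))
    km <- minibatch_kmeans(z, k_meta, rng_seed = derive_seed(rng_seed, 1L))
    used <- sort(unique(km$assignment))
    centers <- km$centers[used, , drop = FALSE]
    z_meta <- pca_project(centers, min(n_pcs, nrow(centers) - 1L))
    meta_memb <- leiden_on_knn(z_meta, knn_k, resolution,
                               derive_seed(rng_seed, 2L))
    memb <- meta_memb[match(km$assignment, used)]
  }
  labs <- as.integer(factor(memb, levels = unique(memb))) - 1L
  n_clusters <- length(unique(labs))
  if (n_clusters == 1L) {
    warning("Leiden clustering produced a single cluster")
  }
  structure(list(assignments = labs, n_clusters = n_clusters),
            class = "cluster_labels")
}

#' Drop homotypic simulated doublets
#'
#' A simulated doublet is homotypic when its two parent cells fall in the
#' same cluster; such doublets resemble singlets and are removed from the
#' positive set. The test uses the clusters of the *parents* (real rows),
#' not the simulated row's own cluster.
#'
#' @param parents integer matrix (n_sim x 2) of parent row indices into the
#'   real rows.
#' @param clusters a `cluster_labels` object (or integer vector) covering
#'   all augmented rows, real rows first.
#' @return logical keep-mask over the simulated rows (TRUE = heterotypic,
#'   kept).
#' @export
exclude_homotypic <- function(parents, clusters) {
  a <- if (inherits(clusters, "cluster_labels")) clusters$assignments else clusters
  a[parents[, 1L]] != a[parents[, 2L]]
}
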