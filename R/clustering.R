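# Cluster assignment from an embedding or a neighbor graph: k-means
# (best of n_init k-means++ seeded Lloyd runs) and spectral clustering
# on the symmetric normalized Laplacian.

cluster_assignment <- function(cell_ids, labels, K, method, seed,
                               quality = NULL, params = list()) {
  structure(
    list(cell_ids = cell_ids, labels = canonical_labels(labels),
         K = K, method = method, seed = seed, quality = quality,
         params = params),
    class = "schic_clusters"
  )
}

#' @export
print.schic_clusters <- function(x, ...) {
  cat("scHi-C clustering (", x$method, "): ", length(x$cell_ids),
      " cells in K = ", x$K, " clusters\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
summary.schic_clusters <- function(object, ...) {
  cat("method:", object$method, " K:", object$K, " seed:",
      object$seed, "\n")
  if (!is.null(object$quality)) {
    if (object$method == "kmeans")
      cat("inertia:", format(object$quality), "\n")
    else
      cat("eigengap:", format(object$quality), "\n")
  }
  print(table(cluster = object$labels))
  invisible(object)
}

# relabel to first-occurrence order starting at 0, so any permutation
# of cluster identities maps to the same canonical output
canonical_labels <- function(labels) {
  u <- unique(labels)
  as.integer(match(labels, u) - 1L)
}

# features matrix from an embedding or a kNN graph (graph: weight rows
# are the features, i.e. the samples x samples matrix is clustered
# directly)
cluster_features <- function(x) {
  if (inherits(x, "schic_embedding"))
    list(ids = x$cell_ids, feats = as.matrix(x$features))
  else if (inherits(x, "schic_knn_graph"))
    list(ids = x$cell_ids, feats = x$weights)
  else stop("expected an schic_embedding or schic_knn_graph")
}

# k-means++ center choice (Arthur & Vassilvitskii seeding) under the
# current RNG state
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- numeric(K)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(K - 1)) {
    if (sum(d2) > 0) {
      centers[j + 1] <- sample.int(n, 1, prob = d2 / sum(d2))
    } else {
      # all remaining points coincide with a chosen center
      free <- setdiff(seq_len(n), centers[seq_len(j)])
      centers[j + 1] <- if (length(free) > 1) sample(free, 1) else free
    }
    nd <- rowSums((x - matrix(x[centers[j + 1], ], n, ncol(x),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' k-means clustering of cells
#'
#' Best of `n_init` Lloyd runs, each started from k-means++ seeded
#' centers drawn from the seeded RNG; the run with the lowest total
#' within-cluster sum of squares (inertia) wins. Deterministic given
#' `seed`.
#'
#' @param x An `schic_embedding` or `schic_knn_graph` (for a graph, the
#'   weight rows are used as features).
#' @param K Number of clusters, `K <= n_cells`.
#' @param seed Integer RNG seed.
#' @param n_init Number of independent k-means++ starts.
#' @param max_iter Maximum Lloyd iterations per start.
#' @return An `schic_clusters` object; `quality` holds the inertia.
#' @export
kmeans_cluster <- function(x, K, seed = 1, n_init = 10, max_iter = 300) {
  cf <- cluster_features(x)
  n <- nrow(cf$feats)
  if (K > n) stop("K must not exceed the number of cells")
  if (K < 1) stop("K must be >= 1")
  fit <- with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      centers <- kmeanspp_centers(cf$feats, K)
      km <- suppressWarnings(
        stats::kmeans(cf$feats, centers = centers, iter.max = max_iter,
                      algorithm = "Lloyd")
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  cluster_assignment(cf$ids, fit$cluster, K, "kmeans", seed,
                     quality = fit$tot.withinss,
                     params = list(n_init = n_init, max_iter = max_iter))
}

#' Spectral clustering of cells
#'
#' Builds the symmetric normalized Laplacian
#' L = I - D^(-1/2) W D^(-1/2) of a non-negative affinity graph, takes
#' the K eigenvectors of its smallest eigenvalues (signs fixed:
#' largest-magnitude entry positive), unit-normalizes the rows and runs
#' seeded k-means on them. A graph with exactly K connected components
#' has K zero eigenvalues whose indicator eigenvectors make the
#' component split exact.
#'
#' @param x An `schic_knn_graph`, or an `schic_embedding` (then an
#'   internal Euclidean kNN graph with `k = max(10, ceil(log2 n))` is
#'   built first).
#' @param K Number of clusters.
#' @param seed Integer RNG seed for the k-means step.
#' @param n_init,max_iter Passed to the k-means step.
#' @return An `schic_clusters` object; `quality` holds the eigengap
#'   (eigenvalue K+1 minus eigenvalue K).
#' @export
spectral_cluster <- function(x, K, seed = 1, n_init = 10, max_iter = 300) {
  if (inherits(x, "schic_embedding")) {
    n <- length(x$cell_ids)
    x <- exact_knn(x, k = min(max(10, ceiling(log2(n))), n - 1))
  }
  stopifnot(inherits(x, "schic_knn_graph"))
  W <- x$weights
  n <- nrow(W)
  if (K > n) stop("K must not exceed the number of cells")
  deg <- rowSums(W)
  if (any(deg == 0))
    stop("isolated vertex in the graph: cell ",
         paste(x$cell_ids[deg == 0], collapse = ", "))
  dhalf <- 1 / sqrt(deg)
  L <- diag(n) - (dhalf * W) * rep(dhalf, each = n)
  L <- (L + t(L)) / 2
  ev <- eigen(L, symmetric = TRUE)
  ord <- seq(n, n - K + 1)               # smallest K eigenvalues
  U <- ev$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(U))) {
    if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
  }
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  vals <- rev(ev$values)
  eigengap <- if (K < n) vals[K + 1] - vals[K] else NA_real_
  km <- kmeans_cluster(embedding_matrix(x$cell_ids, U, "spectral_rows"),
                       K, seed = seed, n_init = n_init, max_iter = max_iter)
  cluster_assignment(x$cell_ids, km$labels, K, "spectral", seed,
                     quality = eigengap,
                     params = list(k = x$k, metric = x$metric))
}

#' Write a cluster assignment as TSV
#'
#' @param assignment An `schic_clusters` object.
#' @param path Output TSV path (columns cell_id, label).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(assignment, path) {
  stopifnot(inherits(assignment, "schic_clusters"))
  utils::write.table(
    data.frame(cell_id = assignment$cell_ids, label = assignment$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
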