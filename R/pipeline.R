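#' One-call embedding + clustering pipeline
#'
#' Convenience wrapper chaining a dimension-reduction scheme and a
#' clustering method, the two choices every cell-clustering run needs.
#'
#' @param container A [scool_container()].
#' @param K Number of clusters.
#' @param embedding One of `"svl"`, `"minhash"`, `"pca"`,
#'   `"compartments"`, `"raw"`, `"knn"`.
#' @param method `"kmeans"` or `"spectral"`.
#' @param seed Integer seed driving every stochastic step.
#' @param k Neighbors for the `knn`/`minhash` graphs (default
#'   `max(10, ceil(log2 n))`).
#' @param num_hashes MinHash signature length.
#' @param distance_threshold Short/long boundary for `svl` (bp).
#' @param n_components Components for `pca` (default: number of bins,
#'   capped).
#' @return An `schic_clusters` object.
#' @examples
#' sim <- simulate_cells(simulation_spec(cells_per_cluster = 5,
#'                                       reads_per_cell = 2000))
#' cl <- schic_cluster(sim$container, K = 3, embedding = "svl",
#'                     method = "kmeans", seed = 7)
#' adjusted_rand_index(cl$labels, sim$truth$labels)
#' @export
schic_cluster <- function(container, K,
                          embedding = c("svl", "minhash", "pca",
                                        "compartments", "raw", "knn"),
                          method = c("kmeans", "spectral"),
                          seed = 1, k = NULL, num_hashes = 800,
                          distance_threshold = 2e6, n_components = NULL) {
  embedding <- match.arg(embedding)
  method <- match.arg(method)
  n <- length(container$cells)
  if (is.null(k)) k <- min(max(10, ceiling(log2(max(n, 2)))), n - 1)
  x <- switch(embedding,
    raw = flatten_cells(container),
    pca = pca_reduce(flatten_cells(container), n_components = n_components),
    svl = svl_features(container, distance_threshold = distance_threshold),
    compartments = compartment_features(container),
    knn = exact_knn(flatten_cells(container), k = k),
    minhash = minhash_knn(container, k = k, num_hashes = num_hashes,
                          seed = seed)
  )
  if (method == "kmeans") kmeans_cluster(x, K, seed = seed)
  else spectral_cluster(x, K, seed = seed)
}
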