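# MinHash locality-sensitive hashing for approximate nearest neighbors.
#
# Each cell is reduced to the SET of its non-zero pixel positions in
# the flattened upper-triangle index space (count magnitudes ignored,
# which makes the similarity robust to coverage differences). For two
# sets the probability that one random min-wise hash agrees equals
# their Jaccard similarity, so the fraction of matching signature slots
# is an unbiased Jaccard estimate; the kNN graph is built on these
# estimates, never materializing the cells x features matrix.

# signature matrix (num_hashes x n_cells) of universal hash functions
# h_i(x) = (a_i x' + b_i) mod p, p prime > universe size. The affine
# family alone is only approximately min-wise independent and is
# systematically biased on arithmetically structured sets — which
# pixel index sets are (runs of consecutive flat indices, and affine
# maps preserve such progressions) — so all hashes share one seeded
# random permutation of the universe, x' = pi(x), applied first.
minhash_signatures <- function(feature_sets, universe, num_hashes, seed) {
  p <- next_prime(universe)
  if (p * p >= 2^53)
    stop("feature universe too large for exact modular hashing")
  draws <- with_seed(seed, {
    list(perm = sample.int(universe),
         a = sample.int(p - 1L, num_hashes, replace = TRUE),
         b = sample.int(p, num_hashes, replace = TRUE) - 1)
  })
  ab <- draws
  sig <- matrix(NA_real_, num_hashes, length(feature_sets))
  for (c in seq_along(feature_sets)) {
    x <- draws$perm[feature_sets[[c]] + 1L] - 1L
    H <- (outer(x, ab$a) %% p + rep(ab$b, each = length(x))) %% p
    tH <- t(H)   # num_hashes x |set|
    jmin <- max.col(-tH, ties.method = "first")
    sig[, c] <- tH[cbind(seq_len(num_hashes), jmin)]
  }
  sig
}

#' MinHash approximate k-nearest neighbors
#'
#' Estimates pairwise Jaccard similarities between cells' non-zero
#' pixel sets from `num_hashes` min-wise hash signatures and links each
#' cell to its `k` most similar cells (ties by cell index); the graph
#' is symmetrized by element-wise maximum. Deterministic given `seed`.
#'
#' @param container A [scool_container()]; every cell needs at least
#'   one non-zero pixel.
#' @param k Neighbors per cell, `k < n_cells`.
#' @param num_hashes Number of hash functions (default 800); the
#'   estimator's standard error shrinks as 1/sqrt(num_hashes).
#' @param seed Integer seed for the hash coefficients.
#' @return An `schic_knn_graph` (metric `jaccard_estimate`, weights in
#'   `[0, 1]`).
#' @export
minhash_knn <- function(container, k, num_hashes = 800, seed = 1) {
  stopifnot(inherits(container, "schic_scool"))
  n <- length(container$cells)
  if (k >= n) stop("k must be smaller than the number of cells")
  nb <- container$binning$n_bins
  sets <- lapply(container$cells, function(cell) {
    px <- cell$pixels[cell$pixels$count != 0, , drop = FALSE]
    if (nrow(px) == 0L)
      stop("cell ", cell$cell_id,
           " has no non-zero pixels; apply filter_cells() first")
    flat_pixel_index(px$bin1_id, px$bin2_id, nb)
  })
  universe <- nb * (nb + 1) / 2
  sig <- minhash_signatures(sets, universe, num_hashes, seed)
  S <- minhash_similarity(sig)
  W <- matrix(0, n, n)
  for (c in seq_len(n)) {
    ord <- order(-S[c, -c], seq_len(n)[-c])
    nbr <- (seq_len(n)[-c])[ord[seq_len(k)]]
    W[c, nbr] <- S[c, nbr]
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  knn_graph(cell_ids(container), W, k, "jaccard_estimate")
}

# n x n matrix of estimated Jaccard similarities (fraction of matching
# signature slots)
minhash_similarity <- function(sig) {
  n <- ncol(sig)
  S <- diag(1, n)
  for (i in seq_len(n - 1)) {
    block <- sig[, (i + 1):n, drop = FALSE] == sig[, i]
    S[i, (i + 1):n] <- S[(i + 1):n, i] <- colMeans(block)
  }
  S
}

#' Estimated Jaccard similarity matrix of a container
#'
#' The full cells x cells matrix of MinHash-estimated Jaccard
#' similarities between non-zero pixel sets (mainly for diagnostics and
#' validation of the estimator).
#'
#' @inheritParams minhash_knn
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
minhash_similarity_matrix <- function(container, num_hashes = 800, seed = 1) {
  stopifnot(inherits(container, "schic_scool"))
  nb <- container$binning$n_bins
  sets <- lapply(container$cells, function(cell) {
    px <- cell$pixels[cell$pixels$count != 0, , drop = FALSE]
    if (nrow(px) == 0L)
      stop("cell ", cell$cell_id, " has no non-zero pixels")
    flat_pixel_index(px$bin1_id, px$bin2_id, nb)
  })
  sig <- minhash_signatures(sets, nb * (nb + 1) / 2, num_hashes, seed)
  S <- minhash_similarity(sig)
  dimnames(S) <- list(cell_ids(container), cell_ids(container))
  S
}
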