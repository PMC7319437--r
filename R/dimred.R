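# Dimension reduction: cells x features embeddings (raw, PCA, SVL,
# compartments) and cells x cells neighbor graphs (exact kNN, MinHash).
#
# Single-cell Hi-C matrices are far too high-dimensional to cluster
# directly (a 1 Mb genome-wide matrix flattens to ~bins^2/2 features),
# so every clustering route goes through one of these reductions.

embedding_matrix <- function(cell_ids, features, method, params = list()) {
  structure(
    list(cell_ids = cell_ids, features = features,
         method = method, params = params),
    class = "schic_embedding"
  )
}

#' @export
print.schic_embedding <- function(x, ...) {
  cat("scHi-C embedding (", x$method, "): ", length(x$cell_ids),
      " cells x ", ncol(x$features), " features\n", sep = "")
  invisible(x)
}

knn_graph <- function(cell_ids, weights, k, metric) {
  structure(
    list(cell_ids = cell_ids, weights = weights, k = k, metric = metric),
    class = "schic_knn_graph"
  )
}

#' @export
print.schic_knn_graph <- function(x, ...) {
  cat("kNN graph (", x$metric, "): ", length(x$cell_ids),
      " cells, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Flatten cells to a raw feature matrix
#'
#' Row c is the flattened upper-triangle pixel vector of cell c in the
#' fixed global row-major pixel ordering; stored sparsely. This is the
#' "no dimension reduction" route: n_bins * (n_bins + 1) / 2 features.
#'
#' @param container A non-empty [scool_container()].
#' @return An `schic_embedding` (method `raw`, sparse feature matrix).
#' @export
flatten_cells <- function(container) {
  stopifnot(inherits(container, "schic_scool"))
  if (length(container$cells) == 0L) stop("container has no cells")
  n <- container$binning$n_bins
  d <- n * (n + 1) / 2
  ii <- jj <- xx <- vector("list", length(container$cells))
  for (c in seq_along(container$cells)) {
    px <- container$cells[[c]]$pixels
    ii[[c]] <- rep.int(c, nrow(px))
    jj[[c]] <- flat_pixel_index(px$bin1_id, px$bin2_id, n) + 1
    xx[[c]] <- px$count
  }
  feats <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(length(container$cells), d)
  )
  embedding_matrix(cell_ids(container), feats, "raw",
                   params = list(n_bins = n))
}

#' Principal component analysis of the raw feature matrix
#'
#' Projects the mean-centered raw matrix onto its top principal
#' components. Deterministic: each component's sign is fixed so that
#' its largest-magnitude loading is positive.
#'
#' @param embedding A raw `schic_embedding` (or any embedding with a
#'   feature matrix).
#' @param n_components Number of components; defaults to the number of
#'   genome bins, capped at `min(n_cells, n_features)`.
#' @return An `schic_embedding` (method `pca`) of the PC scores.
#' @export
pca_reduce <- function(embedding, n_components = NULL) {
  stopifnot(inherits(embedding, "schic_embedding"))
  x <- as.matrix(embedding$features)
  cap <- min(nrow(x), ncol(x))
  if (is.null(n_components))
    n_components <- min(embedding$params$n_bins %||% cap, cap)
  if (n_components <= 0) stop("n_components must be positive")
  n_components <- min(n_components, cap)
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  scores <- sweep(scores, 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  embedding_matrix(embedding$cell_ids, scores, "pca",
                   params = list(n_components = n_components))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact k-nearest-neighbor graph
#'
#' Euclidean kNN on an embedding's rows. Edge weight to a selected
#' neighbor is 1 / (1 + distance); ties are broken by cell index and
#' the graph is symmetrized by element-wise maximum. Zero diagonal.
#'
#' @param embedding An `schic_embedding`.
#' @param k Neighbors per cell, `k < n_cells`.
#' @return An `schic_knn_graph` (metric `euclidean`).
#' @export
exact_knn <- function(embedding, k) {
  stopifnot(inherits(embedding, "schic_embedding"))
  n <- length(embedding$cell_ids)
  if (k >= n) stop("k must be smaller than the number of cells")
  if (k < 1) stop("k must be >= 1")
  D <- as.matrix(stats::dist(as.matrix(embedding$features)))
  W <- matrix(0, n, n)
  for (c in seq_len(n)) {
    ord <- order(D[c, -c], seq_len(n)[-c])   # ties by cell index
    nbr <- (seq_len(n)[-c])[ord[seq_len(k)]]
    W[c, nbr] <- 1 / (1 + D[c, nbr])
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  knn_graph(embedding$cell_ids, W, k, "euclidean")
}

#' Short- versus long-range contact ratio per chromosome
#'
#' For each cell and chromosome the ratio of short-range
#' (0 < genomic distance <= `distance_threshold`) to long-range
#' (distance > threshold) intra-chromosomal contact counts; the main
#' diagonal is excluded. This reduces each cell to n_chromosomes
#' features and is invariant to per-cell sequencing depth.
#'
#' @param container A [scool_container()].
#' @param distance_threshold Short/long boundary in base pairs
#'   (default 2 Mb, separating sub-TAD from long-range scales); must be
#'   at least one bin.
#' @param sentinel Value used when a cell has no long-range contacts on
#'   a chromosome (flagged in `params$sentinel_cells`).
#' @return An `schic_embedding` (method `svl`), one column per
#'   chromosome. Chromosomes too short to have any long-range pixel are
#'   flagged in `params$degenerate_chroms`.
#' @export
svl_features <- function(container, distance_threshold = 2e6,
                         sentinel = 1e6) {
  stopifnot(inherits(container, "schic_scool"))
  binning <- container$binning
  if (distance_threshold < binning$bin_size)
    stop("distance_threshold must be at least one bin")
  thr_bins <- distance_threshold / binning$bin_size
  ci <- bin_chrom_index(binning)
  n_chrom <- length(binning$chrom_names)
  nb <- chrom_n_bins(binning)
  degenerate <- binning$chrom_names[nb - 1 <= thr_bins]
  if (length(degenerate))
    warning("chromosome(s) with no possible long-range pixel at this ",
            "threshold: ", paste(degenerate, collapse = ", "))
  feats <- matrix(NA_real_, length(container$cells), n_chrom,
                  dimnames = list(NULL, binning$chrom_names))
  sentinel_cells <- character()
  for (c in seq_along(container$cells)) {
    px <- container$cells[[c]]$pixels
    c1 <- ci[px$bin1_id + 1L]
    intra <- c1 == ci[px$bin2_id + 1L]
    dist_bins <- px$bin2_id - px$bin1_id
    for (ch in seq_len(n_chrom)) {
      sel <- intra & c1 == ch & dist_bins > 0
      short <- sum(px$count[sel & dist_bins <= thr_bins])
      long <- sum(px$count[sel & dist_bins > thr_bins])
      if (long == 0) {
        feats[c, ch] <- sentinel
        sentinel_cells <- union(sentinel_cells,
                                container$cells[[c]]$cell_id)
      } else {
        feats[c, ch] <- short / long
      }
    }
  }
  embedding_matrix(cell_ids(container), feats, "svl",
                   params = list(distance_threshold = distance_threshold,
                                 sentinel = sentinel,
                                 sentinel_cells = sentinel_cells,
                                 degenerate_chroms = degenerate))
}

#' Observed / expected intra-chromosomal matrix
#'
#' The expected value at bin distance d is the mean observed count over
#' all pixels of that chromosome at distance d (zeros included); each
#' entry is divided by its distance's expectation (0 where the
#' expectation is 0). Removes the dominant distance-decay signal so
#' that compartment structure becomes visible.
#'
#' @param cell A [cell_matrix()].
#' @param binning The [genome_binning()].
#' @param chromosome Chromosome name.
#' @return Dense symmetric matrix over that chromosome's bins.
#' @export
obs_exp <- function(cell, binning, chromosome) {
  chi <- match(chromosome, binning$chrom_names)
  if (is.na(chi)) stop("unknown chromosome: ", chromosome)
  offs <- chrom_offsets(binning)
  idx <- (offs[chi] + 1L):offs[chi + 1L]
  M <- dense_matrix(cell, binning)[idx, idx, drop = FALSE]
  nb <- nrow(M)
  out <- matrix(0, nb, nb)
  d_of <- abs(row(M) - col(M))
  for (d in 0:(nb - 1)) {
    sel <- d_of == d
    expected <- mean(M[sel & upper.tri(M, diag = TRUE)])
    if (expected > 0) out[sel] <- M[sel] / expected
  }
  out
}

# first principal component (largest-eigenvalue eigenvector) of the
# obs/exp Pearson correlation matrix of one chromosome; NULL when
# fewer than 3 unmasked bins.
compartment_track_chrom <- function(cell, binning, chromosome) {
  OE <- obs_exp(cell, binning, chromosome)
  nb <- nrow(OE)
  sds <- apply(OE, 2, stats::sd)
  unmasked <- which(sds > 0)
  if (length(unmasked) < 3) return(NULL)
  C <- stats::cor(OE[, unmasked, drop = FALSE])
  C[!is.finite(C)] <- 0
  ev <- eigen(C, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  track <- numeric(nb)
  track[unmasked] <- v
  track
}

#' Per-cell A/B compartment tracks
#'
#' For each cell and chromosome: observed/expected matrix, Pearson
#' correlation matrix over its columns (zero-variance columns masked to
#' 0), first eigenvector of the correlation matrix, sign oriented so
#' its dot product with the reference track (the same procedure applied
#' to `reference`, by default the pooled bulk matrix) is non-negative;
#' tracks are concatenated across chromosomes into one n_bins vector
#' per cell. The sign of the track separates the two large chromosomal
#' compartments (active/inactive).
#'
#' @param container A [scool_container()].
#' @param reference A [cell_matrix()] used for sign orientation;
#'   defaults to [pool_to_bulk()] of the container.
#' @return An `schic_embedding` (method `compartments`, n_bins
#'   columns). Chromosomes with fewer than 3 unmasked bins yield a
#'   zero-filled segment and are flagged in `params$degenerate`.
#' @export
compartment_features <- function(container, reference = NULL) {
  stopifnot(inherits(container, "schic_scool"))
  if (length(container$cells) == 0L) stop("container has no cells")
  binning <- container$binning
  if (is.null(reference)) reference <- pool_to_bulk(container)
  stopifnot(inherits(reference, "schic_cell"))
  ref_tracks <- lapply(binning$chrom_names, function(ch)
    compartment_track_chrom(reference, binning, ch))
  names(ref_tracks) <- binning$chrom_names
  degenerate <- character()
  feats <- matrix(0, length(container$cells), binning$n_bins)
  offs <- chrom_offsets(binning)
  for (c in seq_along(container$cells)) {
    for (chi in seq_along(binning$chrom_names)) {
      ch <- binning$chrom_names[chi]
      tr <- compartment_track_chrom(container$cells[[c]], binning, ch)
      if (is.null(tr)) {
        degenerate <- union(degenerate,
                            paste0(container$cells[[c]]$cell_id, ":", ch))
        next
      }
      ref <- ref_tracks[[ch]]
      if (!is.null(ref) && sum(tr * ref) < 0) tr <- -tr
      feats[c, (offs[chi] + 1L):offs[chi + 1L]] <- tr
    }
  }
  embedding_matrix(cell_ids(container), feats, "compartments",
                   params = list(degenerate = degenerate))
}
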