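# Seeded generator of single-cell Hi-C containers with known cluster
# structure. Cells of a cluster share a contact-decay exponent and,
# optionally, a compartment checkerboard; reads are placed multinomially
# over intra-chromosomal pixel weights, which is the statistical
# structure count matrices can expose (no read-level simulation).

#' Specification of a synthetic scHi-C experiment
#'
#' Defaults describe the reference simulation used throughout the
#' package's validation: a 100 Mb two-chromosome genome at 1 Mb
#' resolution, three clusters of 50 cells with 50 000 reads each,
#' cluster decay exponents 0.8 / 1.2 / 1.6 and single-cell-strength
#' compartment checkerboards (10 Mb blocks, contrast 0.8) whose phases
#' are offset by one third of the checkerboard period per cluster so
#' the three patterns are pairwise distinct.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp.
#' @param decay_exponents Per-cluster contact-decay exponents
#'   `alpha_k > 0`: pixel (i,j) of a cluster-k cell has sampling weight
#'   proportional to `(1 + |i-j|)^(-alpha_k)`, modulated by the
#'   compartment pattern.
#' @param cells_per_cluster Cells per cluster (recycled to K).
#' @param reads_per_cell Either a single count (every cell gets exactly
#'   that many reads) or `list(meanlog=, sdlog=)` for lognormal totals.
#' @param compartment_contrast Per-cluster contrast `epsilon >= 0`
#'   (recycled): weights are multiplied by `max(0, 1 + epsilon * c)`
#'   where `c = +1` if both bins fall in the same checkerboard
#'   compartment and `-1` otherwise. 0 disables the pattern.
#' @param compartment_block_size Checkerboard block width in bp.
#' @param compartment_phase Per-cluster phase offset in bins (recycled)
#'   shifting the checkerboard, so clusters can differ by compartment
#'   structure alone.
#' @param seed Integer seed; the whole simulation is deterministic
#'   given the spec and seed.
#' @return An object of class `schic_sim_spec`.
#' @export
simulation_spec <- function(chrom_lengths = c(chr1 = 60e6, chr2 = 40e6),
                            bin_size = 1e6,
                            decay_exponents = c(0.8, 1.2, 1.6),
                            cells_per_cluster = 50,
                            reads_per_cell = 50000,
                            compartment_contrast = 0.8,
                            compartment_block_size = 10e6,
                            compartment_phase = c(0, 7, 13),
                            seed = 1) {
  K <- length(decay_exponents)
  if (any(decay_exponents <= 0)) stop("decay exponents must be positive")
  cells_per_cluster <- rep_len(as.integer(cells_per_cluster), K)
  compartment_contrast <- rep_len(compartment_contrast, K)
  compartment_phase <- rep_len(as.integer(compartment_phase), K)
  if (any(compartment_contrast < 0)) stop("compartment contrast must be >= 0")
  if (is.numeric(reads_per_cell) && length(reads_per_cell) == 1) {
    if (reads_per_cell < 0) stop("reads_per_cell must be >= 0")
  } else if (!is.list(reads_per_cell) ||
             !all(c("meanlog", "sdlog") %in% names(reads_per_cell))) {
    stop("reads_per_cell must be a count or list(meanlog=, sdlog=)")
  }
  structure(
    list(chrom_lengths = chrom_lengths, bin_size = bin_size,
         K = K, decay_exponents = decay_exponents,
         cells_per_cluster = cells_per_cluster,
         reads_per_cell = reads_per_cell,
         compartment_contrast = compartment_contrast,
         compartment_block_size = compartment_block_size,
         compartment_phase = compartment_phase,
         seed = as.integer(seed)),
    class = "schic_sim_spec"
  )
}

#' @export
print.schic_sim_spec <- function(x, ...) {
  cat("scHi-C simulation spec: K =", x$K, "clusters x",
      paste(x$cells_per_cluster, collapse = "/"), "cells, alpha =",
      paste(x$decay_exponents, collapse = "/"), "\n")
  invisible(x)
}

# per-cluster sampling weights over intra-chromosomal upper-triangle
# pixels; returns data.frame(bin1_id, bin2_id, weight)
cluster_pixel_weights <- function(spec, binning, k) {
  alpha <- spec$decay_exponents[k]
  eps <- spec$compartment_contrast[k]
  block_bins <- max(1L, as.integer(spec$compartment_block_size /
                                     binning$bin_size))
  phase <- spec$compartment_phase[k]
  offs <- chrom_offsets(binning)
  nb <- chrom_n_bins(binning)
  parts <- lapply(seq_along(nb), function(ci) {
    within <- 0:(nb[ci] - 1L)
    pairs <- which(upper.tri(diag(nb[ci]), diag = TRUE), arr.ind = TRUE)
    i <- pairs[, 1] - 1L
    j <- pairs[, 2] - 1L
    w <- (1 + (j - i))^(-alpha)
    if (eps > 0) {
      comp <- ((within + phase) %/% block_bins) %% 2L
      same <- comp[i + 1L] == comp[j + 1L]
      w <- w * pmax(0, 1 + eps * ifelse(same, 1, -1))
    }
    data.frame(bin1_id = offs[ci] + i, bin2_id = offs[ci] + j, weight = w)
  })
  do.call(rbind, parts)
}

#' Simulate a single-cell Hi-C container with known clusters
#'
#' Draws each cell's reads multinomially over its cluster's pixel
#' weights (distance decay times optional compartment checkerboard);
#' deterministic at bit level given the spec (which carries the seed).
#'
#' @param spec A [simulation_spec()].
#' @return List with `container` (a [scool_container()]) and `truth`
#'   (an `schic_clusters` assignment of the generating clusters).
#' @export
simulate_cells <- function(spec) {
  stopifnot(inherits(spec, "schic_sim_spec"))
  binning <- genome_binning(spec$chrom_lengths, spec$bin_size)
  weights <- lapply(seq_len(spec$K), function(k)
    cluster_pixel_weights(spec, binning, k))
  n_cells <- sum(spec$cells_per_cluster)
  cells <- vector("list", n_cells)
  labels <- integer(n_cells)
  with_seed(spec$seed, {
    idx <- 0L
    for (k in seq_len(spec$K)) {
      wk <- weights[[k]]
      prob <- wk$weight / sum(wk$weight)
      for (i in seq_len(spec$cells_per_cluster[k])) {
        idx <- idx + 1L
        n_reads <- if (is.list(spec$reads_per_cell)) {
          round(stats::rlnorm(1, spec$reads_per_cell$meanlog,
                              spec$reads_per_cell$sdlog))
        } else spec$reads_per_cell
        counts <- as.vector(stats::rmultinom(1, n_reads, prob))
        nz <- counts > 0
        cells[[idx]] <- cell_matrix(
          sprintf("cell_%03d", idx),
          data.frame(bin1_id = wk$bin1_id[nz], bin2_id = wk$bin2_id[nz],
                     count = counts[nz])
        )
        labels[idx] <- k - 1L
      }
    }
  })
  container <- scool_container(
    binning, cells,
    provenance = sprintf("simulated: K=%d alpha=%s seed=%d", spec$K,
                         paste(spec$decay_exponents, collapse = "/"),
                         spec$seed)
  )
  truth <- cluster_assignment(cell_ids(container), labels, spec$K,
                              "truth", spec$seed)
  list(container = container, truth = truth)
}
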