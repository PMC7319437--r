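# In-code fixtures shared across the suite; everything is generated,
# nothing is read from disk.

# one-chromosome binning: n bins of `bin` bp
toy_binning <- function(n = 4, bin = 1e6, name = "chr1") {
  genome_binning(stats::setNames(n * bin, name), bin)
}

# cell from a triplet matrix rbind(c(b1, b2, count), ...)
toy_cell <- function(id, triplets, value_kind = "raw-count") {
  if (is.null(triplets) || length(triplets) == 0) {
    px <- data.frame(bin1_id = integer(), bin2_id = integer(),
                     count = numeric())
  } else {
    px <- data.frame(bin1_id = triplets[, 1], bin2_id = triplets[, 2],
                     count = triplets[, 3])
  }
  cell_matrix(id, px, value_kind = value_kind)
}

# random valid container: <= max_cells cells over <= max_bins bins
# split over 1-2 chromosomes, integer counts
random_container <- function(seed, max_cells = 20, max_bins = 200) {
  set.seed(seed)
  n_chrom <- sample(1:2, 1)
  bin <- 1e6
  nb <- sample(2:max_bins, n_chrom, replace = TRUE)
  lengths <- stats::setNames(nb * bin, paste0("chr", seq_len(n_chrom)))
  gb <- genome_binning(lengths, bin)
  n_cells <- sample(0:max_cells, 1)
  cells <- lapply(seq_len(n_cells), function(c) {
    n_px <- sample(0:30, 1)
    b1 <- sample(0:(gb$n_bins - 1), n_px, replace = TRUE)
    b2 <- pmin(b1 + sample(0:5, n_px, replace = TRUE), gb$n_bins - 1)
    px <- unique(data.frame(bin1_id = pmin(b1, b2), bin2_id = pmax(b1, b2)))
    px$count <- sample(1:50, nrow(px), replace = TRUE)
    cell_matrix(sprintf("cell_%02d", c), px)
  })
  scool_container(gb, cells, provenance = sprintf("random seed %d", seed))
}

# dense symmetric matrix -> cell (drops zeros)
cell_from_dense <- function(id, m, value_kind = "raw-count") {
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  toy_cell(id, cbind(idx[, 1] - 1L, idx[, 2] - 1L, m[idx]),
           value_kind = value_kind)
}

dense_of <- function(cell, binning) schicr:::dense_matrix(cell, binning)

# small reference simulation used by several tests
small_sim <- function(seed = 5, cells = 6, reads = 3000,
                      alphas = c(0.8, 1.2, 1.6), ...) {
  simulate_cells(simulation_spec(decay_exponents = alphas,
                                 cells_per_cluster = cells,
                                 reads_per_cell = reads, seed = seed, ...))
}
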