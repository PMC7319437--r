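# Independent oracles for set-similarity checks: exact Jaccard and an
# exact-Jaccard kNN graph built by the same rule as minhash_knn, plus
# the realistic-density fixture they are evaluated on.

exact_jaccard_matrix <- function(container) {
  nb <- container$binning$n_bins
  sets <- lapply(container$cells, function(cell)
    cell$pixels$bin1_id * nb + cell$pixels$bin2_id)
  n <- length(sets)
  J <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    J[i, j] <- J[j, i] <-
      length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
  }
  J
}

# cell whose non-zero pixels sit at chosen bin pairs of one chromosome
set_cell <- function(id, pairs) {
  toy_cell(id, cbind(pairs, 1))
}

# the fixture for neighbor-recall checks: ~50 cells with lognormal
# per-cell coverage at realistic (10-20%) matrix density, so that
# exact-Jaccard neighborhoods are graded rather than exchangeable
recall_fixture <- function(seed = 33) {
  simulate_cells(simulation_spec(
    cells_per_cluster = 17,
    reads_per_cell = list(meanlog = log(1500), sdlog = 0.6),
    seed = seed))$container
}

# exact-Jaccard kNN graph by the same construction rule as minhash_knn
exact_jaccard_knn <- function(J, k) {
  n <- nrow(J)
  W <- matrix(0, n, n)
  for (c in seq_len(n)) {
    ord <- order(-J[c, -c], seq_len(n)[-c])
    nbr <- (seq_len(n)[-c])[ord[seq_len(k)]]
    W[c, nbr] <- J[c, nbr]
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  W
}

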