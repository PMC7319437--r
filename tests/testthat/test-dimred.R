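test_that("flatten_cells lays out the upper triangle row-major", {
  gb <- toy_binning(3)                 # 6 upper-triangle positions
  a <- toy_cell("a", rbind(c(0, 0, 1), c(1, 2, 5)))
  b <- toy_cell("b", rbind(c(0, 2, 7)))
  a2 <- toy_cell("a2", rbind(c(0, 0, 1), c(1, 2, 5)))
  emb <- flatten_cells(scool_container(gb, list(a, b, a2)))
  expect_equal(dim(emb$features), c(3, 6))
  f <- as.matrix(emb$features)
  expect_equal(f[1, ], c(1, 0, 0, 0, 5, 0))   # (0,0)=1, (1,2)=5
  expect_equal(f[2, 3], 7)                    # (0,2) is position 3
  expect_equal(f[1, ], f[3, ])                # identical cells, identical rows
})

test_that("raw feature count scales as bins^2 / 2", {
  gb <- toy_binning(2702)
  emb <- flatten_cells(scool_container(gb, list(toy_cell("a", rbind(c(0, 0, 1))))))
  d <- ncol(emb$features)
  expect_equal(d, 2702 * 2703 / 2)
  expect_gt(d, 1e6)                           # millions of dimensions
  expect_lt(d, 1e7)
})

test_that("pca_reduce is deterministic and distance-preserving at full rank", {
  set.seed(1)
  x <- matrix(rnorm(12 * 30), 12)
  emb <- schicr:::embedding_matrix(sprintf("c%02d", 1:12), x, "raw",
                                   params = list(n_bins = 30))
  p <- pca_reduce(emb, n_components = 11)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(as.matrix(dist(p$features)), as.matrix(dist(xc)),
               tolerance = 1e-8)
  # rank-1 data: one component carries ~all variance
  line <- outer(seq_len(8), rnorm(30))
  emb1 <- schicr:::embedding_matrix(sprintf("c%d", 1:8), line, "raw",
                                    params = list(n_bins = 30))
  p1 <- pca_reduce(emb1, n_components = 3)
  v <- apply(p1$features, 2, var)
  expect_gt(v[1] / sum(v), 0.999)
  # duplicated cells map to identical rows
  dup <- rbind(x, x[1, ])
  pd <- pca_reduce(schicr:::embedding_matrix(sprintf("c%d", 1:13), dup, "raw",
                                             params = list(n_bins = 30)), 5)
  expect_equal(pd$features[13, ], pd$features[1, ], tolerance = 1e-10)
  expect_error(pca_reduce(emb, n_components = 0), "positive")
})

test_that("exact_knn applies the tie rule and the 1/(1+d) kernel", {
  # 3 exactly equidistant cells (unit basis vectors), k = 1
  pts <- diag(3)
  emb <- schicr:::embedding_matrix(c("a", "b", "c"), pts, "pca")
  g <- exact_knn(emb, k = 1)
  w <- 1 / (1 + sqrt(2))                       # all distances sqrt(2)
  expect_equal(g$weights,
               matrix(c(0, w, w, w, 0, 0, w, 0, 0), 3), tolerance = 1e-12)
  expect_error(exact_knn(emb, k = 3), "smaller")
  # two tight far-apart groups: no cross-group weight
  set.seed(2)
  grp <- rbind(matrix(rnorm(10, 0, 0.01), 5),
               matrix(rnorm(10, 100, 0.01), 5))
  g2 <- exact_knn(schicr:::embedding_matrix(sprintf("c%d", 1:10), grp, "pca"),
                  k = 4)
  expect_true(all(g2$weights[1:5, 6:10] == 0))
  # k = n - 1: fully connected
  g3 <- exact_knn(emb, k = 2)
  expect_true(all(g3$weights[upper.tri(g3$weights)] > 0))
  # row degree bounded by 2k after symmetrization
  expect_true(all(rowSums(g2$weights != 0) <= 8))
  expect_true(all(rowSums(g2$weights != 0) >= 1))
})

test_that("svl_features computes short/long ratios per chromosome", {
  gb <- toy_binning(4)
  cell <- toy_cell("c", rbind(c(0, 1, 4), c(0, 3, 2)))
  emb <- svl_features(scool_container(gb, list(cell)),
                      distance_threshold = 2e6)
  expect_equal(unname(emb$features[1, "chr1"]), 2.0)   # short 4 / long 2
  # scaling all counts x10 leaves ratios unchanged
  cell10 <- toy_cell("c", rbind(c(0, 1, 40), c(0, 3, 20)))
  emb10 <- svl_features(scool_container(gb, list(cell10)),
                        distance_threshold = 2e6)
  expect_equal(emb10$features, emb$features)
  # diagonal excluded; long = 0 yields the flagged sentinel
  diag_cell <- toy_cell("d", rbind(c(0, 0, 9), c(0, 1, 3)))
  embd <- svl_features(scool_container(gb, list(diag_cell)),
                       distance_threshold = 2e6)
  expect_equal(unname(embd$features[1, 1]), embd$params$sentinel)
  expect_equal(embd$params$sentinel_cells, "d")
  # chromosome shorter than the threshold for every pixel: warning + flag
  expect_warning(
    svl_features(scool_container(toy_binning(2), list(diag_cell)),
                 distance_threshold = 2e6),
    "long-range")
})

test_that("obs_exp divides by the per-distance mean including zeros", {
  gb <- toy_binning(3)
  # d0: 4,4,4 ; d1: 2,6 ; d2: 1
  cell <- toy_cell("c", rbind(c(0, 0, 4), c(1, 1, 4), c(2, 2, 4),
                              c(0, 1, 2), c(1, 2, 6), c(0, 2, 1)))
  oe <- obs_exp(cell, gb, "chr1")
  expect_equal(diag(oe), c(1, 1, 1))
  expect_equal(oe[1, 2], 0.5)        # 2 / mean(2, 6)
  expect_equal(oe[2, 3], 1.5)
  expect_equal(oe[1, 3], 1)
  expect_true(isSymmetric(oe))
  # constant per diagonal: all ones
  const <- toy_cell("k", rbind(c(0, 0, 3), c(1, 1, 3), c(2, 2, 3),
                               c(0, 1, 5), c(1, 2, 5), c(0, 2, 2)))
  expect_equal(obs_exp(const, gb, "chr1"), matrix(1, 3, 3))
  # an absent diagonal stays zero
  sparse <- toy_cell("s", rbind(c(0, 0, 1), c(1, 1, 1), c(2, 2, 1)))
  oes <- obs_exp(sparse, gb, "chr1")
  expect_equal(oes[1, 2], 0)
  expect_error(obs_exp(cell, gb, "chr9"), "unknown")
})

# block checkerboard matrix: within-block enriched, cross depleted
checkerboard_cell <- function(id, nb, block, hi = 10, lo = 1, phase = 0) {
  comp <- (((seq_len(nb) - 1 + phase) %/% block) %% 2)
  m <- ifelse(outer(comp, comp, "=="), hi, lo)
  diag(m) <- hi
  cell_from_dense(id, m)
}

test_that("compartment tracks recover the checkerboard sign pattern", {
  nb <- 12
  gb <- toy_binning(nb)
  cellA <- checkerboard_cell("A", nb, 3)
  cont <- scool_container(gb, list(cellA))
  emb <- compartment_features(cont, reference = cellA)
  track <- emb$features[1, ]
  comp <- ((seq_len(nb) - 1) %/% 3) %% 2
  expect_true(all(tapply(sign(track), comp, function(s) length(unique(s))) == 1))
  expect_true(sign(track[1]) != sign(track[4]))
  # a cell identical to the reference gets the reference track exactly
  ref_emb <- compartment_features(scool_container(gb, list(cellA)))
  expect_equal(ref_emb$features[1, ], track, tolerance = 1e-8)
})

test_that("a phase-flipped checkerboard is anti-correlated before orientation", {
  nb <- 12
  gb <- toy_binning(nb)
  cellA <- checkerboard_cell("A", nb, 3)
  cellB <- checkerboard_cell("B", nb, 3, phase = 3)   # flipped phase
  emb <- compartment_features(scool_container(gb, list(cellA, cellB)),
                              reference = cellA)
  trA <- emb$features[1, ]
  trB <- emb$features[2, ]
  # orientation forces non-negative dot with the reference track
  expect_gte(sum(trB * trA), 0)
  expect_gt(abs(stats::cor(trA, trB)), 0.9)
})

test_that("chromosomes with too few usable bins yield flagged zero segments", {
  gb <- genome_binning(c(chr1 = 12e6, chr2 = 2e6), 1e6)
  cellA <- checkerboard_cell("A", 12, 3)     # chr2 left empty
  emb <- compartment_features(scool_container(gb, list(cellA)),
                              reference = cellA)
  expect_equal(emb$features[1, 13:14], c(0, 0))
  expect_true(any(grepl("chr2", emb$params$degenerate)))
})
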