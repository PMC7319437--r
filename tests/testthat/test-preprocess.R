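test_that("normalize_smallest equalizes totals and is idempotent", {
  gb <- toy_binning(4)
  cells <- lapply(c(300, 120, 200), function(t)
    toy_cell(paste0("c", t), rbind(c(0, 1, t))))
  cont <- scool_container(gb, cells)
  norm <- normalize_smallest(cont)
  expect_equal(sapply(norm$cells, total_reads), rep(120, 3),
               ignore_attr = TRUE)
  again <- normalize_smallest(norm)
  expect_equal(lapply(again$cells, `[[`, "pixels"),
               lapply(norm$cells, `[[`, "pixels"))
  # single cell and equal totals: values unchanged
  one <- normalize_smallest(scool_container(gb, cells[1]))
  expect_equal(one$cells[[1]]$pixels$count, 300)
  # zero-total cell: directed to QC
  bad <- scool_container(gb, c(cells, list(toy_cell("z", NULL))))
  expect_error(normalize_smallest(bad), "filter_cells")
})

test_that("normalize_range01 and normalize_scale behave per definition", {
  cell <- toy_cell("c", rbind(c(0, 1, 2), c(0, 2, 4), c(1, 2, 8)))
  r <- normalize_range01(cell)
  expect_equal(r$pixels$count, c(0.25, 0.5, 1.0))
  expect_equal(r$value_kind, "normalized")
  # max already 1: unchanged
  expect_equal(normalize_range01(r)$pixels$count, r$pixels$count)
  expect_error(normalize_range01(toy_cell("z", NULL)), "all-zero")
  expect_equal(normalize_scale(cell, 1)$pixels$count, cell$pixels$count)
  expect_equal(total_reads(normalize_scale(cell, 2)), 2 * total_reads(cell))
  expect_error(normalize_scale(cell, 0), "positive")
})

# independent brute-force ICE oracle: raw row-sum iteration to 1e-10,
# bias renormalized to geometric mean 1
ice_oracle <- function(A, iters = 500) {
  b <- rep(1, nrow(A))
  W <- A
  for (i in seq_len(iters)) {
    s <- rowSums(W)
    step <- s / mean(s)
    b <- b * step
    W <- W / outer(step, step)
  }
  b <- b / exp(mean(log(b)))
  list(bias = b, corrected = A / outer(b, b))
}

test_that("ice_correct matches the brute-force iteration oracle", {
  gb <- toy_binning(2)
  for (A in list(matrix(c(2, 1, 1, 2), 2),
                 matrix(c(4, 1, 1, 2), 2))) {
    res <- ice_correct(cell_from_dense("t", A), gb, tol = 1e-10)
    expect_true(res$converged)
    oracle <- ice_oracle(A)
    expect_equal(res$bias, oracle$bias, tolerance = 1e-6)
    expect_equal(dense_of(res$matrix, gb), oracle$corrected,
                 tolerance = 1e-6)
    s <- rowSums(dense_of(res$matrix, gb))
    expect_lt(stats::sd(s) / mean(s), 1e-9)
  }
})

test_that("an already balanced matrix is a fixed point with unit biases", {
  gb <- toy_binning(2)
  res <- ice_correct(cell_from_dense("b", matrix(c(2, 1, 1, 2), 2)), gb)
  expect_equal(res$bias, c(1, 1))
  expect_equal(res$iterations, 1L)
})

test_that("all-zero bins are masked and excluded from balancing", {
  gb <- toy_binning(3)
  A <- matrix(0, 3, 3)
  A[1, 1] <- 2; A[1, 2] <- A[2, 1] <- 1; A[2, 2] <- 2  # bin 2 empty
  res <- ice_correct(cell_from_dense("m", A), gb)
  expect_equal(res$masked, c(FALSE, FALSE, TRUE))
  expect_true(is.na(res$bias[3]))
  M <- dense_of(res$matrix, gb)
  expect_true(all(M[3, ] == 0) && all(M[, 3] == 0))
})

test_that("kr_correct reaches unit row sums; diag(4) has the closed form", {
  gb <- toy_binning(2)
  res <- kr_correct(cell_from_dense("d", diag(c(4, 4))), gb)
  expect_true(res$converged)
  expect_equal(res$bias, c(2, 2), tolerance = 1e-6)     # x = a_ii^(-1/2)
  expect_equal(diag(dense_of(res$matrix, gb)), c(1, 1), tolerance = 1e-6)

  A <- matrix(c(2, 1, 1, 2), 2)
  kr <- kr_correct(cell_from_dense("t", A), gb)
  expect_equal(rowSums(dense_of(kr$matrix, gb)), c(1, 1), tolerance = 1e-6)
  # agreement with ICE up to a single global scalar
  ice <- ice_correct(cell_from_dense("t", A), gb, tol = 1e-10)
  ratio <- dense_of(ice$matrix, gb) / dense_of(kr$matrix, gb)
  expect_lt(diff(range(ratio)), 1e-4 * mean(ratio))
  expect_error(kr_correct(toy_cell("z", NULL), gb), "zero")
})

test_that("non-balanceable support is reported as an error", {
  # star support: rows 2,3 touch only row 1 -> no diagonal scaling with
  # unit row sums exists
  gb3 <- toy_binning(3)
  star <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3)
  expect_error(kr_correct(cell_from_dense("star", star), gb3,
                          max_iter = 500),
               "not balanceable")
  # with a second, disconnected component the offender is named
  gb5 <- toy_binning(5)
  A <- matrix(0, 5, 5)
  A[1:3, 1:3] <- star
  A[4, 5] <- A[5, 4] <- 1
  expect_error(kr_correct(cell_from_dense("disc", A), gb5, max_iter = 500),
               "disconnected support component")
  # disconnected but balanceable support converges per component
  D <- diag(c(4, 9, 16))
  res <- kr_correct(cell_from_dense("diag3", D), gb3)
  expect_true(res$converged)
  expect_equal(diag(dense_of(res$matrix, gb3)), rep(1, 3), tolerance = 1e-6)
})

test_that("ICE and KR corrections are proportional on positive matrices", {
  gb <- toy_binning(10)
  set.seed(42)
  for (r in 1:5) {
    A <- matrix(stats::runif(100, 0.5, 5), 10)
    A <- (A + t(A)) / 2
    cell <- cell_from_dense("p", round(A * 100), value_kind = "raw-count")
    ice <- ice_correct(cell, gb, tol = 1e-9)
    kr <- kr_correct(cell, gb, tol = 1e-9)
    Mi <- dense_of(ice$matrix, gb)
    Mk <- dense_of(kr$matrix, gb)
    ratio <- Mi[Mk != 0] / Mk[Mk != 0]
    expect_lt(max(abs(ratio / mean(ratio) - 1)), 1e-4)
  }
})

test_that("balancing is scale-equivariant", {
  gb <- toy_binning(5)
  set.seed(7)
  A <- matrix(stats::rpois(25, 10) + 1, 5)
  A <- A + t(A)
  c1 <- ice_correct(cell_from_dense("a", A), gb, tol = 1e-9)
  c2 <- ice_correct(cell_from_dense("b", 3 * A), gb, tol = 1e-9)
  M1 <- dense_of(c1$matrix, gb)
  M2 <- dense_of(c2$matrix, gb)
  ratio <- M2[M1 != 0] / M1[M1 != 0]
  expect_lt(diff(range(ratio)), 1e-6 * mean(ratio))
})

test_that("merge_bins groups runs of n bins and conserves totals", {
  cont <- random_container(11)
  for (n in c(1, 2, 3)) {
    merged <- merge_bins(cont, n)
    expect_equal(sapply(merged$cells, total_reads),
                 sapply(cont$cells, total_reads))
  }
  # 5-bin chromosome, n = 2: 3 merged bins, the last from a single bin
  gb5 <- toy_binning(5)
  c5 <- scool_container(gb5, list(toy_cell("c", rbind(c(0, 4, 3)))))
  m <- merge_bins(c5, 2)
  expect_equal(m$binning$n_bins, 3)
  expect_equal(m$cells[[1]]$pixels,
               data.frame(bin1_id = 0L, bin2_id = 2L, count = 3))
  # 4-bin chromosome, n = 2: 2 bins
  expect_equal(merge_bins(scool_container(toy_binning(4), list()), 2)$binning$n_bins, 2)
  expect_error(merge_bins(cont, 0), ">= 1")
})

test_that("adjust_chromosomes restricts and re-indexes bins", {
  gb <- genome_binning(c(chr1 = 3e6, chr2 = 2e6, chrY = 1e6), 1e6)
  cell <- toy_cell("c", rbind(c(0, 1, 2),    # chr1-chr1
                              c(0, 3, 5),    # chr1-chr2
                              c(3, 5, 7)))   # chr2-chrY
  cont <- scool_container(gb, list(cell))
  keep_all <- adjust_chromosomes(cont, keep = c("chr1", "chr2", "chrY"))
  expect_equal(keep_all$cells[[1]]$pixels, cell$pixels)
  no_y <- adjust_chromosomes(cont, remove = "chrY")
  expect_equal(no_y$binning$chrom_names, c("chr1", "chr2"))
  expect_equal(no_y$binning$n_bins, 5)
  expect_equal(nrow(no_y$cells[[1]]$pixels), 2)   # chr2-chrY pixel dropped
  chr1 <- adjust_chromosomes(cont, keep = "chr1")
  expect_equal(chr1$binning$n_bins, 3)
  expect_equal(chr1$cells[[1]]$pixels$count, 2)
  expect_error(adjust_chromosomes(cont, keep = "chr9"), "unknown")
  expect_error(adjust_chromosomes(cont, keep = "chr1", remove = "chrY"),
               "exactly one")
})
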