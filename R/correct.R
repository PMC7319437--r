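# Matrix balancing: iterative correction (ICE) and a Knight-Ruiz-style
# doubly stochastic scaling. Both find per-bin factors b such that
# diag(1/b) A diag(1/b) has equal row sums; they differ only in the
# normalization of the result (ICE: geometric-mean-1 biases; KR: row
# sums exactly 1) and the inner iteration.

balancing_result <- function(cell, bias, masked, iterations, converged) {
  structure(
    list(matrix = cell, bias = bias, masked = masked,
         iterations = iterations, converged = converged),
    class = "schic_balancing"
  )
}

#' @export
print.schic_balancing <- function(x, ...) {
  cat("Balancing of '", x$matrix$cell_id, "': ",
      if (x$converged) "converged" else "NOT converged",
      " after ", x$iterations, " iteration(s), ",
      sum(x$masked), " masked bin(s)\n", sep = "")
  invisible(x)
}

# rebuild the corrected cell from raw pixels and a bias vector;
# masked rows/columns are dropped (zeroed).
apply_bias <- function(cell, bias, masked) {
  px <- cell$pixels
  keep <- !masked[px$bin1_id + 1L] & !masked[px$bin2_id + 1L]
  px <- px[keep, , drop = FALSE]
  px$count <- px$count / (bias[px$bin1_id + 1L] * bias[px$bin2_id + 1L])
  cell_matrix(cell$cell_id, px, value_kind = "corrected")
}

#' Iterative correction (ICE)
#'
#' Plain row-sum iteration: each pass divides the working matrix by the
#' outer product of (row sum / mean row sum) until the coefficient of
#' variation of the unmasked row sums falls below `tol`. The final bias
#' vector is renormalized to geometric mean 1 over unmasked bins and
#' the corrected matrix recomputed as raw / (bias_i * bias_j).
#'
#' @param cell A [cell_matrix()] (upper-triangle storage interpreted
#'   symmetrically).
#' @param binning The [genome_binning()] of the container.
#' @param max_iter Maximum number of passes.
#' @param tol Convergence threshold on the row-sum coefficient of
#'   variation.
#' @param mask_zero_bins Mask bins whose full row is zero (default on).
#' @return A `schic_balancing` result: corrected matrix (`value_kind`
#'   `corrected`), `bias` (NA on masked bins), `masked`, `iterations`,
#'   `converged`.
#' @export
ice_correct <- function(cell, binning, max_iter = 1000, tol = 1e-5,
                        mask_zero_bins = TRUE) {
  stopifnot(inherits(cell, "schic_cell"), inherits(binning, "schic_binning"))
  A <- dense_matrix(cell, binning)
  n <- nrow(A)
  masked <- if (mask_zero_bins) rowSums(A) == 0 else rep(FALSE, n)
  if (all(masked)) stop("all bins are empty; nothing to balance")
  W <- A[!masked, !masked, drop = FALSE]
  bias_sub <- rep(1, nrow(W))
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    s <- rowSums(W)
    if (any(s == 0))
      stop("zero row sum on an unmasked bin; enable mask_zero_bins")
    cv <- stats::sd(s) / mean(s)
    if (is.na(cv)) cv <- 0   # single unmasked bin
    if (cv < tol) { converged <- TRUE; break }
    step <- s / mean(s)
    bias_sub <- bias_sub * step
    W <- W / outer(step, step)
  }
  # geometric mean 1 over unmasked bins
  bias_sub <- bias_sub / exp(mean(log(bias_sub)))
  bias <- rep(NA_real_, n)
  bias[!masked] <- bias_sub
  b_eff <- ifelse(masked, 1, bias)
  balancing_result(apply_bias(cell, b_eff, masked), bias, masked,
                   iterations, converged)
}

# connected components of the support graph of a symmetric matrix
support_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(W[u, ] != 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Knight-Ruiz balancing
#'
#' Finds a positive diagonal scaling x with diag(x) A diag(x) doubly
#' stochastic (all unmasked row sums 1), via the symmetric fixed-point
#' iteration x <- sqrt(x / (A x)), which converges for matrices with
#' irreducible non-negative support. The reported bias is 1/x so the
#' corrected value is raw / (bias_i * bias_j), as for [ice_correct()].
#'
#' @param cell A [cell_matrix()].
#' @param binning The [genome_binning()] of the container.
#' @param tol Convergence threshold: max |row sum - 1| of the corrected
#'   matrix.
#' @param max_iter Maximum iterations.
#' @param mask_zero_bins Mask all-zero bins before balancing.
#' @return A `schic_balancing` result; unmasked row sums of the
#'   corrected matrix equal 1 within `tol` when `converged`.
#' @export
kr_correct <- function(cell, binning, tol = 1e-6, max_iter = 10000,
                       mask_zero_bins = TRUE) {
  stopifnot(inherits(cell, "schic_cell"), inherits(binning, "schic_binning"))
  A <- dense_matrix(cell, binning)
  n <- nrow(A)
  masked <- if (mask_zero_bins) rowSums(A) == 0 else rep(FALSE, n)
  if (all(masked)) stop("matrix is entirely zero; cannot balance")
  W <- A[!masked, !masked, drop = FALSE]
  x <- 1 / sqrt(rowSums(W))
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    Ax <- as.vector(W %*% x)
    s <- x * Ax
    if (max(abs(s - 1)) < tol) { converged <- TRUE; break }
    x <- sqrt(x / Ax)
  }
  if (!converged) {
    # a diagonal scaling to unit row sums need not exist (the support
    # must have total support); report the support structure
    comp <- support_components(W)
    unmasked_ids <- which(!masked) - 1L
    detail <- if (max(comp) > 1L) {
      small <- which(comp == which.min(tabulate(comp)))
      paste0("; disconnected support component of bins {",
             paste(unmasked_ids[small], collapse = ", "), "}")
    } else ""
    stop("matrix support is not balanceable: Knight-Ruiz iteration did ",
         "not reach tol after ", max_iter, " iterations", detail)
  }
  bias <- rep(NA_real_, n)
  bias[!masked] <- 1 / x
  b_eff <- ifelse(masked, 1, bias)
  balancing_result(apply_bias(cell, b_eff, masked), bias, masked,
                   iterations, converged)
}

#' Balance every cell of a container
#'
#' @param container A [scool_container()].
#' @param method `"ice"` or `"kr"`.
#' @param ... Passed to [ice_correct()] or [kr_correct()].
#' @return The container with corrected cells; per-cell convergence
#'   flags are recorded in the provenance log.
#' @export
correct_cells <- function(container, method = c("ice", "kr"), ...) {
  method <- match.arg(method)
  fn <- if (method == "ice") ice_correct else kr_correct
  results <- lapply(container$cells, fn, binning = container$binning, ...)
  cells <- lapply(results, function(r) r$matrix)
  n_conv <- sum(vapply(results, function(r) r$converged, logical(1)))
  scool_container(container$binning, cells,
                  provenance = c(container$provenance,
                                 sprintf("correct: %s (%d/%d converged)",
                                         method, n_conv, length(results))))
}
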