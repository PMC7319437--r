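# small shared helpers

# Evaluate `expr` under a private RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# 0-based flat index of an upper-triangle pixel (b1 <= b2, 0-based)
# in row-major order over the n*(n+1)/2 positions.
flat_pixel_index <- function(b1, b2, n_bins) {
  b1 * n_bins - b1 * (b1 - 1) / 2 + (b2 - b1)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovered cluster labels against a known truth. 1 is
#' perfect agreement, 0 the expectation under independent random
#' labellings.
#'
#' @param a,b Two label vectors of equal length (any atomic type).
#' @return Numeric scalar in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# smallest prime strictly greater than x (trial division; x modest)
next_prime <- function(x) {
  p <- as.numeric(x) + 1
  is_prime <- function(q) {
    if (q < 2) return(FALSE)
    if (q %% 2 == 0) return(q == 2)
    d <- 3
    while (d * d <= q) {
      if (q %% d == 0) return(FALSE)
      d <- d + 2
    }
    TRUE
  }
  while (!is_prime(p)) p <- p + 1
  p
}
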