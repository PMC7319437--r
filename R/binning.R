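#' Genome binning at fixed resolution
#'
#' Builds the coordinate system shared by every contact matrix: each
#' chromosome is cut into consecutive bins of `bin_size` base pairs
#' (0-based, half-open intervals; the last bin of a chromosome may be
#' shorter). Global bin ids are 0-based and increase in (chromosome
#' order, start).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in
#'   base pairs; names are the chromosome identifiers, order is kept.
#' @param bin_size Bin width in base pairs (positive integer).
#' @return An object of class `schic_binning` with fields `chrom_names`,
#'   `chrom_lengths`, `bin_size`, `bins` (data.frame chrom/start/end) and
#'   `n_bins`.
#' @examples
#' gb <- genome_binning(c(chr1 = 5e6, chr2 = 3e6), bin_size = 1e6)
#' gb$n_bins
#' @export
genome_binning <- function(chrom_lengths, bin_size) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicated chromosome names")
  if (any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1)
    stop("bin_size must be a positive integer")

  chrom_names <- names(chrom_lengths)
  per_chrom <- lapply(seq_along(chrom_names), function(ci) {
    len <- chrom_lengths[[ci]]
    starts <- seq(0L, len - 1L, by = bin_size)
    data.frame(
      chrom = chrom_names[ci],
      start = as.numeric(starts),
      end   = pmin(starts + bin_size, len),
      stringsAsFactors = FALSE
    )
  })
  bins <- do.call(rbind, per_chrom)
  rownames(bins) <- NULL

  structure(
    list(
      chrom_names   = chrom_names,
      chrom_lengths = as.numeric(chrom_lengths),
      bin_size      = bin_size,
      bins          = bins,
      n_bins        = nrow(bins)
    ),
    class = "schic_binning"
  )
}

#' @export
print.schic_binning <- function(x, ...) {
  cat("Genome binning:", length(x$chrom_names), "chromosome(s),",
      x$n_bins, "bins of", x$bin_size, "bp\n")
  invisible(x)
}

# Number of bins per chromosome, in chromosome order.
chrom_n_bins <- function(binning) {
  as.integer(ceiling(binning$chrom_lengths / binning$bin_size))
}

# 0-based global bin id of the first bin of each chromosome, plus a
# terminal n_bins entry (cooler-style chrom_offset index).
chrom_offsets <- function(binning) {
  c(0L, cumsum(chrom_n_bins(binning)))
}

# chromosome index (1-based) of each global 0-based bin id
bin_chrom_index <- function(binning) {
  rep.int(seq_along(binning$chrom_names), chrom_n_bins(binning))
}

binning_equal <- function(a, b) {
  identical(a$chrom_names, b$chrom_names) &&
    isTRUE(all.equal(a$chrom_lengths, b$chrom_lengths)) &&
    a$bin_size == b$bin_size &&
    a$n_bins == b$n_bins
}
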