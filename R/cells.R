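#' Single-cell contact matrix
#'
#' One cell's sparse upper-triangular contact matrix as (bin1_id,
#' bin2_id, count) triplets over a shared genome binning. Pixels are
#' stored once per unordered pair with `bin1_id <= bin2_id`, ordered by
#' (bin1_id, bin2_id).
#'
#' @param cell_id Cell identifier (non-empty string).
#' @param pixels data.frame with integer columns `bin1_id`, `bin2_id`
#'   (0-based global bin ids) and numeric `count`.
#' @param value_kind One of `"raw-count"`, `"corrected"`,
#'   `"normalized"`. Raw counts must be non-negative integers.
#' @return An object of class `schic_cell`.
#' @export
cell_matrix <- function(cell_id, pixels,
                        value_kind = c("raw-count", "corrected", "normalized")) {
  value_kind <- match.arg(value_kind)
  if (!is.character(cell_id) || length(cell_id) != 1L || !nzchar(cell_id))
    stop("cell_id must be a non-empty string")
  if (is.null(pixels) || nrow(pixels) == 0L) {
    pixels <- data.frame(bin1_id = integer(), bin2_id = integer(),
                         count = numeric())
  }
  stopifnot(all(c("bin1_id", "bin2_id", "count") %in% names(pixels)))
  pixels <- data.frame(bin1_id = as.integer(pixels$bin1_id),
                       bin2_id = as.integer(pixels$bin2_id),
                       count   = as.numeric(pixels$count))
  if (any(pixels$bin1_id < 0L) || any(pixels$bin2_id < pixels$bin1_id))
    stop("pixels must satisfy 0 <= bin1_id <= bin2_id")
  if (any(pixels$count < 0))
    stop("pixel counts must be non-negative")
  if (value_kind == "raw-count" && any(pixels$count != round(pixels$count)))
    stop("raw-count pixel values must be integers")
  key <- order(pixels$bin1_id, pixels$bin2_id)
  pixels <- pixels[key, , drop = FALSE]
  rownames(pixels) <- NULL
  if (nrow(pixels) > 1L &&
      anyDuplicated(paste(pixels$bin1_id, pixels$bin2_id)))
    stop("duplicate (bin1_id, bin2_id) pixel pairs in cell ", cell_id)
  structure(
    list(cell_id = cell_id, pixels = pixels, value_kind = value_kind),
    class = "schic_cell"
  )
}

#' Total reads of a cell matrix
#'
#' The plain sum of stored pixel values over the upper triangle
#' (diagonal included, off-diagonal pixels counted once — not doubled
#' for symmetry), the quantity quality-control thresholds act on.
#'
#' @param x A `schic_cell`.
#' @return Numeric scalar.
#' @export
total_reads <- function(x) {
  stopifnot(inherits(x, "schic_cell"))
  sum(x$pixels$count)
}

#' @export
print.schic_cell <- function(x, ...) {
  cat("scHi-C cell '", x$cell_id, "': ", nrow(x$pixels), " pixels, total ",
      format(total_reads(x)), " (", x$value_kind, ")\n", sep = "")
  invisible(x)
}

#' Container of single-cell contact matrices
#'
#' An ordered collection of per-cell contact matrices sharing one genome
#' binning — the in-memory twin of the scool HDF5 layout.
#'
#' @param binning A [genome_binning()] object.
#' @param cells List of [cell_matrix()] objects with unique cell ids.
#' @param provenance Character vector logging operations applied.
#' @return An object of class `schic_scool`.
#' @seealso [read_scool()], [write_scool()], [simulate_cells()]
#' @export
scool_container <- function(binning, cells = list(), provenance = character()) {
  stopifnot(inherits(binning, "schic_binning"))
  if (length(cells) > 0) {
    ok <- vapply(cells, inherits, logical(1), what = "schic_cell")
    if (!all(ok)) stop("cells must be a list of schic_cell objects")
    ids <- vapply(cells, function(c) c$cell_id, character(1))
    if (anyDuplicated(ids))
      stop("duplicate cell ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    for (cell in cells) {
      if (nrow(cell$pixels) > 0 && max(cell$pixels$bin2_id) >= binning$n_bins)
        stop("cell ", cell$cell_id, " references bin ids beyond n_bins")
    }
    names(cells) <- ids
  }
  structure(
    list(binning = binning, cells = cells,
         provenance = as.character(provenance)),
    class = "schic_scool"
  )
}

#' @export
print.schic_scool <- function(x, ...) {
  cat("scool container:", length(x$cells), "cell(s) on",
      x$binning$n_bins, "bins (", x$binning$bin_size, "bp,",
      length(x$binning$chrom_names), "chromosome(s))\n")
  invisible(x)
}

#' @export
length.schic_scool <- function(x) length(x$cells)

cell_ids <- function(container) {
  vapply(container$cells, function(c) c$cell_id, character(1), USE.NAMES = FALSE)
}

cell_totals <- function(container) {
  vapply(container$cells, total_reads, numeric(1), USE.NAMES = FALSE)
}

add_provenance <- function(container, entry) {
  container$provenance <- c(container$provenance, entry)
  container
}

#' Pool all cells into one bulk Hi-C matrix
#'
#' Pixel-wise sum of every cell matrix in the container, yielding a
#' single Hi-C interaction matrix that can be analysed like a regular
#' bulk experiment.
#'
#' @param container A [scool_container()] with at least one cell.
#' @param cell_id Identifier given to the pooled matrix.
#' @return A [cell_matrix()] whose total equals the sum of cell totals.
#' @export
pool_to_bulk <- function(container, cell_id = "bulk") {
  stopifnot(inherits(container, "schic_scool"))
  if (length(container$cells) == 0L)
    stop("cannot pool an empty container")
  all_px <- do.call(rbind, lapply(container$cells, function(c) c$pixels))
  key <- all_px$bin1_id * container$binning$n_bins + all_px$bin2_id
  agg <- rowsum(all_px$count, group = key, reorder = TRUE)
  ukey <- as.numeric(rownames(agg))
  kinds <- unique(vapply(container$cells, function(c) c$value_kind, character(1)))
  kind <- if (identical(kinds, "raw-count")) "raw-count" else "normalized"
  cell_matrix(
    cell_id,
    data.frame(bin1_id = ukey %/% container$binning$n_bins,
               bin2_id = ukey %% container$binning$n_bins,
               count = as.numeric(agg)),
    value_kind = kind
  )
}

#' Summarize a container
#'
#' @param container A [scool_container()].
#' @return A list of class `schic_info` with `n_cells`, `n_bins`,
#'   `bin_size`, `chromosomes` and min/median/max per-cell read totals
#'   (`NA` for an empty container).
#' @export
schic_info <- function(container) {
  stopifnot(inherits(container, "schic_scool"))
  totals <- cell_totals(container)
  structure(
    list(
      n_cells = length(container$cells),
      n_bins = container$binning$n_bins,
      bin_size = container$binning$bin_size,
      chromosomes = container$binning$chrom_names,
      min_total = if (length(totals)) min(totals) else NA_real_,
      median_total = if (length(totals)) stats::median(totals) else NA_real_,
      max_total = if (length(totals)) max(totals) else NA_real_
    ),
    class = "schic_info"
  )
}

#' @export
print.schic_info <- function(x, ...) {
  cat("cells:      ", x$n_cells, "\n")
  cat("bins:       ", x$n_bins, " (", x$bin_size, " bp)\n", sep = "")
  cat("chromosomes:", paste(x$chromosomes, collapse = ", "), "\n")
  if (!is.na(x$min_total))
    cat("reads/cell:  min ", format(x$min_total), ", median ",
        format(x$median_total), ", max ", format(x$max_total), "\n", sep = "")
  invisible(x)
}

# Dense symmetric matrix of one cell (whole genome). Off-diagonal pixels
# are mirrored; the diagonal is stored once.
dense_matrix <- function(cell, binning) {
  n <- binning$n_bins
  m <- matrix(0, n, n)
  px <- cell$pixels
  if (nrow(px) > 0) {
    m[cbind(px$bin1_id + 1L, px$bin2_id + 1L)] <- px$count
    m[cbind(px$bin2_id + 1L, px$bin1_id + 1L)] <- px$count
  }
  m
}

# Inverse of dense_matrix: upper-triangle triplets of a symmetric matrix.
pixels_from_dense <- function(m, drop_zero = TRUE) {
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  cnt <- m[idx]
  if (drop_zero) {
    keep <- cnt != 0
    idx <- idx[keep, , drop = FALSE]
    cnt <- cnt[keep]
  }
  data.frame(bin1_id = idx[, 1] - 1L, bin2_id = idx[, 2] - 1L, count = cnt)
}
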