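# Per-cell quality control: read coverage and sparsity.
#
# Sparsity is the fraction of possible intra-chromosomal upper-triangle
# pixels (diagonal included) that carry a non-zero count.
# Inter-chromosomal pixels are ignored here: at the working resolutions
# of single-cell Hi-C they are dominated by noise and the downstream
# analyses are per-chromosome.

intra_possible_pixels <- function(binning) {
  nb <- chrom_n_bins(binning)
  sum(nb * (nb + 1) / 2)
}

is_intra <- function(pixels, binning) {
  ci <- bin_chrom_index(binning)
  ci[pixels$bin1_id + 1L] == ci[pixels$bin2_id + 1L]
}

#' Compute per-cell quality metrics
#'
#' @param container A [scool_container()] with at least one cell.
#' @param min_reads,min_density Thresholds recorded in (and applied by)
#'   the report: a cell passes iff `total_reads >= min_reads` and
#'   `sparsity >= min_density`.
#' @return A data.frame of class `schic_qc` with columns `cell_id`,
#'   `total_reads`, `sparsity`, `pass`, `fail_reason` (one of
#'   `low_reads`, `too_sparse`, `none`; a cell failing both reports
#'   `low_reads`). Thresholds and the sparsity convention are stored as
#'   attributes.
#' @export
compute_qc <- function(container, min_reads = 100000, min_density = 0) {
  stopifnot(inherits(container, "schic_scool"))
  if (length(container$cells) == 0L) stop("container has no cells")
  possible <- intra_possible_pixels(container$binning)
  totals <- cell_totals(container)
  nz_intra <- vapply(container$cells, function(cell) {
    px <- cell$pixels
    if (nrow(px) == 0L) return(0L)
    sum(is_intra(px, container$binning) & px$count != 0)
  }, numeric(1), USE.NAMES = FALSE)
  sparsity <- nz_intra / possible
  pass <- totals >= min_reads & sparsity >= min_density
  fail_reason <- rep("none", length(totals))
  fail_reason[sparsity < min_density] <- "too_sparse"
  fail_reason[totals < min_reads] <- "low_reads"   # first check wins
  out <- data.frame(
    cell_id = cell_ids(container),
    total_reads = totals,
    sparsity = sparsity,
    pass = pass,
    fail_reason = fail_reason,
    stringsAsFactors = FALSE
  )
  attr(out, "min_reads") <- min_reads
  attr(out, "min_density") <- min_density
  attr(out, "sparsity_definition") <-
    "non-zero intra-chromosomal upper-triangle pixels / possible"
  class(out) <- c("schic_qc", "data.frame")
  out
}

#' @export
print.schic_qc <- function(x, ...) {
  cat("scHi-C QC report:", nrow(x), "cells,", sum(x$pass), "pass",
      sprintf("(min_reads=%g, min_density=%g)\n",
              attr(x, "min_reads"), attr(x, "min_density")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Filter cells by read coverage and sparsity
#'
#' Removes interaction matrices of cells whose total read count falls
#' below `min_reads` (the default, 100000, discards cells with fewer
#' than 100 000 reads and keeps the boundary cell) or whose sparsity is
#' below `min_density` (disabled by default; the choice of a sparsity
#' cutoff is left to the user).
#'
#' @param container A [scool_container()].
#' @param min_reads Minimum total reads for a cell to be kept.
#' @param min_density Minimum sparsity (fraction of possible
#'   intra-chromosomal pixels that are non-zero).
#' @return List with `container` (passing cells, original order) and
#'   `report` (the full [compute_qc()] report over the input cells).
#' @export
filter_cells <- function(container, min_reads = 100000, min_density = 0) {
  report <- compute_qc(container, min_reads = min_reads,
                       min_density = min_density)
  keep <- report$pass
  if (!any(keep))
    warning("all cells removed by QC thresholds")
  out <- scool_container(
    container$binning,
    container$cells[keep],
    provenance = c(container$provenance,
                   sprintf("qc: min_reads=%g min_density=%g kept %d/%d",
                           min_reads, min_density, sum(keep), length(keep)))
  )
  list(container = out, report = report)
}

#' Write a QC report as TSV
#'
#' @param report A [compute_qc()] report.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
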