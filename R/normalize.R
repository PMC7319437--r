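# Read-depth normalization, three modes: to the depth of the matrix
# with the least read coverage, to the value range 0..1, or by a
# user-defined scaling factor.

#' Normalize all cells to the smallest read depth
#'
#' Scales every cell by (minimum total / own total) so that all cell
#' totals are equal to the depth of the matrix with the least read
#' coverage. Idempotent.
#'
#' @param container A [scool_container()]; every cell must have a
#'   positive total (run QC first to remove empty cells).
#' @return The container with every cell's `value_kind` set to
#'   `normalized`.
#' @export
normalize_smallest <- function(container) {
  stopifnot(inherits(container, "schic_scool"))
  if (length(container$cells) == 0L) stop("container has no cells")
  totals <- cell_totals(container)
  if (any(totals == 0))
    stop("cells with zero total reads present; apply filter_cells() first")
  target <- min(totals)
  cells <- lapply(container$cells, function(cell) {
    f <- target / sum(cell$pixels$count)
    px <- cell$pixels
    px$count <- px$count * f
    cell_matrix(cell$cell_id, px, value_kind = "normalized")
  })
  scool_container(container$binning, cells,
                  provenance = c(container$provenance,
                                 sprintf("normalize: smallest (target=%g)",
                                         target)))
}

#' Normalize a matrix to the value range 0 to 1
#'
#' @param cell A [cell_matrix()] with a positive maximum value.
#' @return The cell with every value divided by the matrix maximum.
#' @export
normalize_range01 <- function(cell) {
  stopifnot(inherits(cell, "schic_cell"))
  if (nrow(cell$pixels) == 0L || max(cell$pixels$count) <= 0)
    stop("cannot range-normalize an all-zero matrix")
  px <- cell$pixels
  px$count <- px$count / max(px$count)
  cell_matrix(cell$cell_id, px, value_kind = "normalized")
}

#' Scale a matrix by a user-defined factor
#'
#' @param cell A [cell_matrix()].
#' @param factor Positive multiplier.
#' @return The scaled cell (`value_kind` `normalized`).
#' @export
normalize_scale <- function(cell, factor) {
  stopifnot(inherits(cell, "schic_cell"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("factor must be a positive number")
  px <- cell$pixels
  px$count <- px$count * factor
  cell_matrix(cell$cell_id, px, value_kind = "normalized")
}
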