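# Resolution and chromosome adjustment of a whole container.

#' Merge consecutive bins
#'
#' Merges runs of `n` consecutive bins within each chromosome (the last
#' run of a chromosome may be shorter) and sums the counts falling into
#' each merged pixel. Total reads are conserved exactly for every cell.
#'
#' @param container A [scool_container()].
#' @param n Merge factor (integer >= 1); `n = 1` is the identity.
#' @return A container on the coarser binning (`bin_size * n`).
#' @export
merge_bins <- function(container, n) {
  stopifnot(inherits(container, "schic_scool"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("merge factor n must be an integer >= 1")
  if (n == 1L) return(container)
  old <- container$binning
  new_binning <- genome_binning(
    stats::setNames(old$chrom_lengths, old$chrom_names),
    old$bin_size * n
  )
  # map old global bin id -> new global bin id (both 0-based)
  nb_old <- chrom_n_bins(old)
  off_new <- chrom_offsets(new_binning)
  bin_map <- unlist(lapply(seq_along(nb_old), function(ci) {
    within <- seq_len(nb_old[ci]) - 1L
    off_new[ci] + within %/% n
  }), use.names = FALSE)
  cells <- lapply(container$cells, function(cell) {
    px <- cell$pixels
    if (nrow(px) == 0L) return(cell_matrix(cell$cell_id, px, cell$value_kind))
    b1 <- bin_map[px$bin1_id + 1L]
    b2 <- bin_map[px$bin2_id + 1L]
    lo <- pmin(b1, b2); hi <- pmax(b1, b2)
    key <- lo * new_binning$n_bins + hi
    agg <- rowsum(px$count, group = key, reorder = TRUE)
    ukey <- as.numeric(rownames(agg))
    cell_matrix(cell$cell_id,
                data.frame(bin1_id = ukey %/% new_binning$n_bins,
                           bin2_id = ukey %% new_binning$n_bins,
                           count = as.numeric(agg)),
                value_kind = cell$value_kind)
  })
  scool_container(new_binning, cells,
                  provenance = c(container$provenance,
                                 sprintf("merge_bins: n=%d", n)))
}

#' Keep or remove chromosomes
#'
#' Restricts the bin table and every cell's pixels to a chromosome
#' subset; bin ids are re-indexed contiguously. Pixels touching a
#' removed chromosome are dropped.
#'
#' @param container A [scool_container()].
#' @param keep,remove Exactly one of the two: chromosome names to keep
#'   (in original order) or to remove. Unknown names are an error.
#' @return The restricted container.
#' @export
adjust_chromosomes <- function(container, keep = NULL, remove = NULL) {
  stopifnot(inherits(container, "schic_scool"))
  if (is.null(keep) == is.null(remove))
    stop("give exactly one of 'keep' or 'remove'")
  old <- container$binning
  sel <- if (is.null(keep)) remove else keep
  unknown <- setdiff(sel, old$chrom_names)
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  keep_names <- if (is.null(keep)) setdiff(old$chrom_names, remove)
                else old$chrom_names[old$chrom_names %in% keep]
  if (length(keep_names) == 0L) stop("no chromosomes left")
  new_binning <- genome_binning(
    stats::setNames(old$chrom_lengths[match(keep_names, old$chrom_names)],
                    keep_names),
    old$bin_size
  )
  # old global bin id -> new global bin id, NA when dropped
  ci <- bin_chrom_index(old)
  kept_bin <- old$chrom_names[ci] %in% keep_names
  bin_map <- rep(NA_integer_, old$n_bins)
  bin_map[kept_bin] <- seq_len(sum(kept_bin)) - 1L
  cells <- lapply(container$cells, function(cell) {
    px <- cell$pixels
    b1 <- bin_map[px$bin1_id + 1L]
    b2 <- bin_map[px$bin2_id + 1L]
    ok <- !is.na(b1) & !is.na(b2)
    cell_matrix(cell$cell_id,
                data.frame(bin1_id = b1[ok], bin2_id = b2[ok],
                           count = px$count[ok]),
                value_kind = cell$value_kind)
  })
  scool_container(new_binning, cells,
                  provenance = c(container$provenance,
                                 paste("adjust_chromosomes: keep",
                                       paste(keep_names, collapse = ","))))
}
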