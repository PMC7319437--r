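# Per-cluster consensus matrices and per-cell contact-decay profiles.

#' Build per-cluster consensus matrices
#'
#' Merges all matrices of one cluster into a single interaction matrix
#' (pixel-wise sum) and normalizes the resulting consensus matrices to
#' the same read coverage: every consensus is scaled to the smallest
#' pre-normalization cluster total.
#'
#' @param container A [scool_container()].
#' @param assignment An `schic_clusters` covering every cell of the
#'   container.
#' @return An object of class `schic_consensus`: list with `matrices`
#'   (cluster label -> [cell_matrix()]), `member_counts`, and `target`
#'   (the common total).
#' @export
build_consensus <- function(container, assignment) {
  stopifnot(inherits(container, "schic_scool"),
            inherits(assignment, "schic_clusters"))
  ids <- cell_ids(container)
  pos <- match(ids, assignment$cell_ids)
  if (anyNA(pos))
    stop("assignment does not cover cells: ",
         paste(ids[is.na(pos)], collapse = ", "))
  labels <- assignment$labels[pos]
  u <- sort(unique(labels))
  empty <- setdiff(0:(assignment$K - 1L), u)
  if (length(empty))
    warning("empty cluster label(s) skipped: ",
            paste(empty, collapse = ", "))
  sums <- lapply(u, function(lab) {
    members <- container$cells[labels == lab]
    pool_to_bulk(scool_container(container$binning, members),
                 cell_id = paste0("cluster_", lab))
  })
  totals <- vapply(sums, total_reads, numeric(1))
  target <- min(totals)
  mats <- lapply(seq_along(sums), function(i) {
    px <- sums[[i]]$pixels
    px$count <- px$count * (target / totals[i])
    cell_matrix(sums[[i]]$cell_id, px, value_kind = "normalized")
  })
  names(mats) <- as.character(u)
  structure(
    list(matrices = mats,
         member_counts = stats::setNames(tabulate(factor(labels, levels = u)),
                                         as.character(u)),
         target = target,
         binning = container$binning),
    class = "schic_consensus"
  )
}

#' @export
print.schic_consensus <- function(x, ...) {
  cat("Consensus matrices for", length(x$matrices), "cluster(s),",
      "normalized to total", format(x$target), "\n")
  for (nm in names(x$matrices))
    cat("  cluster ", nm, ": ", x$member_counts[[nm]], " cell(s)\n", sep = "")
  invisible(x)
}

#' Contact-decay profiles ordered by cluster
#'
#' For each cell, the distribution of its intra-chromosomal contacts
#' over genomic distance from the main diagonal (distance 0) up to
#' `max_distance`, in bin-size steps; each row is normalized to sum 1
#' so coverage differences do not dominate the comparison of decay
#' shapes. Rows are grouped by cluster label (then input order), the
#' layout of the cluster-profile plot.
#'
#' @param container A [scool_container()].
#' @param assignment An `schic_clusters` covering every cell, or `NULL`
#'   to keep input order in a single group.
#' @param max_distance Maximum genomic distance in base pairs
#'   (default 50 Mb), inclusive; must be at least one bin.
#' @return An object of class `schic_decay`: `cell_ids`, `labels`,
#'   `distances` (bp, 0..max_distance), `values` (cells x distances,
#'   rows sum to 1), `degenerate` (cells with no counts in range, left
#'   as zero rows).
#' @export
decay_profiles <- function(container, assignment = NULL,
                           max_distance = 50e6) {
  stopifnot(inherits(container, "schic_scool"))
  binning <- container$binning
  if (max_distance < binning$bin_size)
    stop("max_distance must be at least one bin")
  max_off <- floor(max_distance / binning$bin_size)
  distances <- (0:max_off) * binning$bin_size
  ci <- bin_chrom_index(binning)
  n <- length(container$cells)
  vals <- matrix(0, n, max_off + 1L)
  degenerate <- character()
  for (c in seq_len(n)) {
    px <- container$cells[[c]]$pixels
    intra <- ci[px$bin1_id + 1L] == ci[px$bin2_id + 1L]
    off <- px$bin2_id - px$bin1_id
    sel <- intra & off <= max_off
    if (any(sel)) {
      row <- vapply(0:max_off, function(d)
        sum(px$count[sel & off == d]), numeric(1))
      s <- sum(row)
      if (s > 0) vals[c, ] <- row / s
      else degenerate <- c(degenerate, container$cells[[c]]$cell_id)
    } else {
      degenerate <- c(degenerate, container$cells[[c]]$cell_id)
    }
  }
  ids <- cell_ids(container)
  if (!is.null(assignment)) {
    pos <- match(ids, assignment$cell_ids)
    if (anyNA(pos)) stop("assignment does not cover all cells")
    labels <- assignment$labels[pos]
    ord <- order(labels, seq_len(n))
  } else {
    labels <- rep(0L, n)
    ord <- seq_len(n)
  }
  structure(
    list(cell_ids = ids[ord], labels = labels[ord],
         distances = distances, values = vals[ord, , drop = FALSE],
         degenerate = degenerate),
    class = "schic_decay"
  )
}

#' @export
print.schic_decay <- function(x, ...) {
  cat("Contact-decay profiles:", length(x$cell_ids), "cells x",
      length(x$distances), "distances (0..",
      max(x$distances) / 1e6, "Mb)\n")
  invisible(x)
}

#' Plot consensus matrices
#'
#' Writes one log-scaled heatmap per consensus matrix plus, always, a
#' TSV of the underlying dense matrix alongside (same base name,
#' `.tsv`).
#'
#' @param consensus An [build_consensus()] result.
#' @param prefix Output path prefix; files are
#'   `<prefix>_cluster_<label>.png` / `.tsv`.
#' @return Character vector of image paths, invisibly.
#' @export
render_consensus <- function(consensus, prefix) {
  stopifnot(inherits(consensus, "schic_consensus"))
  paths <- character()
  for (nm in names(consensus$matrices)) {
    m <- dense_matrix(consensus$matrices[[nm]], consensus$binning)
    tsv <- paste0(prefix, "_cluster_", nm, ".tsv")
    utils::write.table(m, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    png_path <- paste0(prefix, "_cluster_", nm, ".png")
    grDevices::png(png_path, width = 600, height = 600)
    graphics::image(log1p(m)[, rev(seq_len(ncol(m)))],
                    col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                    axes = FALSE,
                    main = paste0("cluster ", nm, " (n = ",
                                  consensus$member_counts[[nm]], ")"))
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  invisible(paths)
}

#' Plot cluster decay profiles
#'
#' Cells-by-distance heatmap with cells grouped by cluster on the
#' x-axis and separators between clusters; the numeric table is always
#' written alongside (`<path>.tsv` with cell_id, label and one column
#' per distance).
#'
#' @param profile A [decay_profiles()] result.
#' @param path Output image path (PNG).
#' @return `path`, invisibly.
#' @export
render_profiles <- function(profile, path) {
  stopifnot(inherits(profile, "schic_decay"))
  tab <- data.frame(cell_id = profile$cell_ids, label = profile$labels,
                    profile$values)
  names(tab)[-(1:2)] <- paste0("d_", profile$distances)
  utils::write.table(tab, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  grDevices::png(path, width = 800, height = 500)
  v <- t(profile$values)                # distances x cells
  graphics::image(x = seq_len(ncol(v)), y = profile$distances / 1e6,
                  z = t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  xlab = "cells (grouped by cluster)",
                  ylab = "distance from diagonal (Mb)")
  breaks <- which(diff(profile$labels) != 0)
  if (length(breaks))
    graphics::abline(v = breaks + 0.5, col = "black", lwd = 2)
  grDevices::dev.off()
  invisible(path)
}
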