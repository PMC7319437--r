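# scool / cool HDF5 serialization (cooler schema v3 field names).
#
# Layout written:
#   /chroms/name, /chroms/length
#   /bins/chrom (0-based index into chroms), /bins/start, /bins/end
#   cool:  /pixels/{bin1_id,bin2_id,count}, /indexes/{chrom_offset,bin1_offset}
#   scool: /cells/<cell_id>/pixels/..., /cells/<cell_id>/indexes/...
# One resolution per file; the root bins table is shared by every cell.

h5_has <- function(path, name) {
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::H5Lexists(fid, name)
}

require_h5 <- function(path, names) {
  for (nm in names) {
    if (!h5_has(path, nm))
      stop("not a valid cool/scool file: missing HDF5 path '", nm,
           "' in ", path)
  }
}

read_binning_h5 <- function(path) {
  chrom_names <- as.character(rhdf5::h5read(path, "chroms/name"))
  chrom_lengths <- as.numeric(rhdf5::h5read(path, "chroms/length"))
  names(chrom_lengths) <- chrom_names
  starts <- as.numeric(rhdf5::h5read(path, "bins/start"))
  ends <- as.numeric(rhdf5::h5read(path, "bins/end"))
  bin_size <- as.integer(max(ends - starts))
  gb <- genome_binning(chrom_lengths, bin_size)
  # verify the stored table matches the reconstructed coordinate system
  chrom_idx <- as.integer(rhdf5::h5read(path, "bins/chrom"))
  stored <- data.frame(chrom = chrom_names[chrom_idx + 1L],
                       start = starts, end = ends, stringsAsFactors = FALSE)
  if (!isTRUE(all.equal(stored, gb$bins, check.attributes = FALSE)))
    stop("bins table in ", path,
         " is not a contiguous fixed-size binning of its chromosomes")
  gb
}

write_binning_h5 <- function(path, binning) {
  rhdf5::h5createGroup(path, "chroms")
  rhdf5::h5write(binning$chrom_names, path, "chroms/name")
  rhdf5::h5write(binning$chrom_lengths, path, "chroms/length")
  rhdf5::h5createGroup(path, "bins")
  chrom_idx <- bin_chrom_index(binning) - 1L
  rhdf5::h5write(chrom_idx, path, "bins/chrom")
  rhdf5::h5write(binning$bins$start, path, "bins/start")
  rhdf5::h5write(binning$bins$end, path, "bins/end")
}

# cooler-style indexes for one pixel table
pixel_indexes <- function(pixels, binning) {
  n <- binning$n_bins
  bin1_offset <- c(0L, cumsum(tabulate(pixels$bin1_id + 1L, nbins = n)))
  offs <- chrom_offsets(binning)
  chrom_offset <- offs
  list(chrom_offset = as.integer(chrom_offset),
       bin1_offset = as.integer(bin1_offset))
}

write_pixels_h5 <- function(path, group, pixels, binning, value_kind) {
  rhdf5::h5createGroup(path, paste0(group, "pixels"))
  rhdf5::h5write(pixels$bin1_id, path, paste0(group, "pixels/bin1_id"))
  rhdf5::h5write(pixels$bin2_id, path, paste0(group, "pixels/bin2_id"))
  rhdf5::h5write(pixels$count, path, paste0(group, "pixels/count"))
  idx <- pixel_indexes(pixels, binning)
  rhdf5::h5createGroup(path, paste0(group, "indexes"))
  rhdf5::h5write(idx$chrom_offset, path, paste0(group, "indexes/chrom_offset"))
  rhdf5::h5write(idx$bin1_offset, path, paste0(group, "indexes/bin1_offset"))
  rhdf5::h5write(value_kind, path, paste0(group, "value_kind"))
}

read_cell_h5 <- function(path, group, cell_id) {
  pixels <- data.frame(
    bin1_id = as.integer(rhdf5::h5read(path, paste0(group, "pixels/bin1_id"))),
    bin2_id = as.integer(rhdf5::h5read(path, paste0(group, "pixels/bin2_id"))),
    count = as.numeric(rhdf5::h5read(path, paste0(group, "pixels/count")))
  )
  vk_path <- paste0(group, "value_kind")
  value_kind <- if (h5_has(path, vk_path))
    as.character(rhdf5::h5read(path, vk_path)) else "raw-count"
  cell_matrix(cell_id, pixels, value_kind = value_kind)
}

#' Write a container to an scool file
#'
#' Serializes the container in the single-resolution cooler layout: one
#' root chroms/bins table plus one `cells/<cell_id>` group per cell
#' holding its pixel table and indexes. Content is deterministic for
#' identical input (no timestamps).
#'
#' @param container A [scool_container()].
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_scool <- function(container, path) {
  stopifnot(inherits(container, "schic_scool"))
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop("cannot create file ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  write_binning_h5(path, container$binning)
  rhdf5::h5write("scool", path, "format")
  if (length(container$provenance))
    rhdf5::h5write(container$provenance, path, "provenance")
  rhdf5::h5createGroup(path, "cells")
  if (length(container$cells))
    rhdf5::h5write(cell_ids(container), path, "cell_order")
  for (cell in container$cells) {
    grp <- paste0("cells/", cell$cell_id, "/")
    rhdf5::h5createGroup(path, sub("/$", "", grp))
    write_pixels_h5(path, grp, cell$pixels, container$binning, cell$value_kind)
  }
  invisible(path)
}

#' Read an scool file
#'
#' @param path Path to an scool HDF5 file written by [write_scool()] or
#'   following the same layout. Cell pixel order is normalized to
#'   ascending (bin1_id, bin2_id).
#' @return A [scool_container()].
#' @export
read_scool <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  require_h5(path, c("chroms/name", "chroms/length",
                     "bins/chrom", "bins/start", "bins/end", "cells"))
  binning <- read_binning_h5(path)
  listing <- rhdf5::h5ls(path, recursive = 2)
  ids <- listing$name[listing$group == "/cells" & listing$otype == "H5I_GROUP"]
  if (h5_has(path, "cell_order")) {
    stored <- as.character(rhdf5::h5read(path, "cell_order"))
    if (setequal(stored, ids)) ids <- stored else ids <- sort(ids)
  } else {
    ids <- sort(ids)
  }
  cells <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    grp <- paste0("cells/", ids[i], "/")
    require_h5(path, paste0(grp, c("pixels/bin1_id", "pixels/bin2_id",
                                   "pixels/count")))
    if (h5_has(path, paste0(grp, "bins"))) {
      cb_start <- as.numeric(rhdf5::h5read(path, paste0(grp, "bins/start")))
      if (!identical(length(cb_start), length(binning$bins$start)) ||
          !isTRUE(all.equal(cb_start, binning$bins$start)))
        stop("cell '", ids[i], "' carries a bins table inconsistent with ",
             "the root bins table; every cell must share one binning")
    }
    cells[[i]] <- read_cell_h5(path, grp, ids[i])
  }
  prov <- if (h5_has(path, "provenance"))
    as.character(rhdf5::h5read(path, "provenance")) else character()
  scool_container(binning, cells, provenance = prov)
}

#' Write a single-cell matrix as a cool file
#'
#' @param cell A [cell_matrix()].
#' @param binning The [genome_binning()] the pixels refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cool <- function(cell, binning, path) {
  stopifnot(inherits(cell, "schic_cell"), inherits(binning, "schic_binning"))
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop("cannot create file ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  write_binning_h5(path, binning)
  rhdf5::h5write("cool", path, "format")
  write_pixels_h5(path, "", cell$pixels, binning, cell$value_kind)
  invisible(path)
}

#' Read a cool file holding one matrix
#'
#' @param path Path to a cool HDF5 file. The cell id is the file base
#'   name with the extension stripped.
#' @return List with elements `cell` ([cell_matrix()]) and `binning`.
#' @export
read_cool <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  require_h5(path, c("chroms/name", "chroms/length", "bins/chrom",
                     "bins/start", "bins/end", "pixels/bin1_id",
                     "pixels/bin2_id", "pixels/count"))
  binning <- read_binning_h5(path)
  cell_id <- sub("\\.[^.]*$", "", basename(path))
  list(cell = read_cell_h5(path, "", cell_id), binning = binning)
}

#' Merge individual cool files into one scool container
#'
#' Every input must be a single-cell cool matrix and all inputs must
#' share an identical bin table. Cell ids are derived from file names
#' (base name, extension stripped); a collision is a hard error.
#'
#' @param cell_paths Character vector of cool file paths, order kept.
#' @return A [scool_container()] with one cell per input file.
#' @export
merge_cells_to_scool <- function(cell_paths) {
  if (length(cell_paths) == 0L) stop("no input files")
  first <- read_cool(cell_paths[[1L]])
  binning <- first$binning
  cells <- vector("list", length(cell_paths))
  cells[[1L]] <- first$cell
  bad <- character()
  for (i in seq_along(cell_paths)[-1L]) {
    cur <- read_cool(cell_paths[[i]])
    if (!binning_equal(binning, cur$binning)) {
      bad <- c(bad, cell_paths[[i]])
      next
    }
    cells[[i]] <- cur$cell
  }
  if (length(bad))
    stop("bin tables inconsistent with ", cell_paths[[1L]], ": ",
         paste(bad, collapse = ", "))
  ids <- vapply(cells, function(c) c$cell_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate cell ids derived from file names: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  scool_container(binning, cells,
                  provenance = paste("merged", length(cells), "cool files"))
}
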