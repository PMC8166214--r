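#' Gene panel
#'
#' An ordered set of gene symbols with a flag marking the marker subset used
#' by the classifiers (in a typical MERFISH design some genes are cell-type
#' markers driving segmentation while the rest are held out for downstream
#' analysis).
#'
#' @param names character vector of unique gene symbols.
#' @param markers character vector (subset of `names`) or logical mask
#'   flagging marker genes. Default: all genes are markers.
#' @return A `jsta_panel` object.
#' @export
gene_panel <- function(names, markers = NULL) {
  names <- as.character(names)
  if (anyDuplicated(names)) stopf("gene panel names must be unique")
  if (is.null(markers)) {
    mask <- rep(TRUE, length(names))
  } else if (is.logical(markers)) {
    stopifnot(length(markers) == length(names))
    mask <- markers
  } else {
    missing <- setdiff(markers, names)
    if (length(missing)) stopf("markers not in panel: %s",
                               paste(missing, collapse = ", "))
    mask <- names %in% markers
  }
  structure(list(names = names, marker_mask = mask), class = "jsta_panel")
}

#' @export
print.jsta_panel <- function(x, ...) {
  cat(sprintf("<jsta_panel> %d genes (%d markers)\n",
              length(x$names), sum(x$marker_mask)))
  invisible(x)
}

#' Build a spot table from coordinates and gene labels
#'
#' @param x,y,z numeric coordinates in micrometers.
#' @param gene integer gene indices (1-based into the panel) or gene symbols.
#' @param panel a [gene_panel()].
#' @param true_cell optional ground-truth cell ids (simulation only).
#' @return data.frame of class `jsta_spots` with columns x, y, z, gene
#'   (integer index) and optionally true_cell; the panel is attached as an
#'   attribute.
#' @export
spot_table <- function(x, y, z, gene, panel, true_cell = NULL) {
  if (is.character(gene) || is.factor(gene)) {
    gene <- match(as.character(gene), panel$names)
  }
  gene <- as.integer(gene)
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   gene = gene)
  if (!is.null(true_cell)) df$true_cell <- as.integer(true_cell)
  if (!all(is.finite(as.matrix(df[c("x", "y", "z")]))))
    stopf("spot coordinates must be finite")
  if (any(is.na(gene)) || any(gene < 1L) || any(gene > length(panel$names)))
    stopf("gene indices out of panel range")
  attr(df, "panel") <- panel
  class(df) <- c("jsta_spots", "data.frame")
  df
}

#' Read a transcript spot table from delimited text
#'
#' Expects a header row. Gene labels not present in the panel are dropped
#' with a message reporting the count.
#'
#' @param path path to a delimited text file.
#' @param panel a [gene_panel()].
#' @param delimiter field delimiter (default tab; `","` for CSV).
#' @param columns named character vector mapping the roles x, y, z, gene
#'   (and optionally true_cell) to column names in the file.
#' @param has_z if `FALSE`, no z column is read and z is set to 0.
#' @return a `jsta_spots` data.frame.
#' @export
read_spots <- function(path, panel, delimiter = "\t",
                       columns = c(x = "x", y = "y", z = "z", gene = "gene"),
                       has_z = TRUE) {
  if (!file.exists(path)) stopf("spot file not found: %s", path)
  df <- read.delim(path, sep = delimiter, header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stopf("spot file is empty: %s", path)
  getcol <- function(role)
    if (role %in% names(columns)) columns[[role]] else role
  need <- c("x", "y", "gene", if (has_z) "z")
  for (role in need) {
    cn <- getcol(role)
    if (!cn %in% names(df)) stopf("missing column '%s' (role %s)", cn, role)
  }
  gx <- df[[getcol("gene")]]
  keep <- if (is.character(gx) || is.factor(gx)) {
    as.character(gx) %in% panel$names
  } else {
    gx >= 1 & gx <= length(panel$names)
  }
  if (any(!keep)) message(sum(!keep), " spot(s) with genes outside the panel dropped")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) stopf("no spots remain after panel filtering")
  tc <- if ("true_cell" %in% names(columns) &&
            columns[["true_cell"]] %in% names(df))
    df[[columns[["true_cell"]]]] else NULL
  spot_table(
    x = df[[getcol("x")]],
    y = df[[getcol("y")]],
    z = if (has_z) df[[getcol("z")]] else 0,
    gene = df[[getcol("gene")]],
    panel = panel, true_cell = tc
  )
}

#' Nuclei seeds
#'
#' A labeled 3D volume of nuclei (0 = background) on the same physical frame
#' as the spot coordinates.
#'
#' @param labels 3D integer array of nucleus labels.
#' @param voxel_size length-3 numeric, micrometers per voxel along x, y, z.
#' @param origin physical coordinate of the volume corner (default 0,0,0).
#' @return A `jsta_nuclei` object with per-nucleus centroids (micrometers).
#' @export
nuclei_seeds <- function(labels, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3, length(voxel_size) == 3)
  labels <- array(as.integer(labels), dim(labels))
  if (any(labels < 0)) stopf("nucleus labels must be non-negative")
  ids <- sort(unique(labels[labels > 0]))
  cent <- matrix(NA_real_, length(ids), 3,
                 dimnames = list(ids, c("x", "y", "z")))
  if (length(ids)) {
    idx <- which(labels > 0)
    ijk <- array_index(idx, dim(labels))
    xyz <- voxel_center_aniso(ijk, origin, voxel_size)
    lab <- labels[idx]
    for (d in 1:3) cent[, d] <- tapply(xyz[, d], lab, mean)[as.character(ids)]
  }
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), ids = ids, centroids = cent),
            class = "jsta_nuclei")
}

voxel_center_aniso <- function(ijk, origin, voxel_size) {
  sweep(sweep(ijk - 0.5, 2, voxel_size, "*"), 2, origin, "+")
}

#' Consolidate per-plane 2D nuclei masks into 3D seeds
#'
#' DAPI nuclei are typically segmented per z plane; this merges the 2D masks
#' into 3D nuclei. 2D masks below `min_area` are removed, masks in adjacent
#' planes are merged when their pixel overlap (shared pixels divided by the
#' smaller mask's pixel count) reaches `overlap_frac`, and merged nuclei
#' spanning fewer than `min_z_extent` planes are removed. Surviving nuclei
#' are relabeled 1..K.
#'
#' @param planes list of 2D integer label matrices (one per z plane), or a
#'   3D integer array sliced along the third dimension.
#' @param z_step plane spacing in micrometers.
#' @param pixel_size lateral pixel size in micrometers.
#' @param min_area minimum 2D mask area in square micrometers (default 10).
#' @param overlap_frac minimum overlap fraction for merging (default 0.30).
#' @param min_z_extent minimum number of planes a 3D nucleus must span
#'   (default 5).
#' @param origin physical coordinate of the volume corner.
#' @return A [nuclei_seeds()] object.
#' @export
consolidate_nuclei_masks <- function(planes, z_step, pixel_size = 1,
                                     min_area = 10, overlap_frac = 0.30,
                                     min_z_extent = 5, origin = c(0, 0, 0)) {
  if (is.array(planes) && length(dim(planes)) == 3)
    planes <- lapply(seq_len(dim(planes)[3]), function(k) planes[, , k])
  shapes <- vapply(planes, function(p) dim(p), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stopf("all planes must share the same shape")
  np <- length(planes)
  nx <- shapes[1, 1]; ny <- shapes[2, 1]

  # per-plane masks above the area threshold become union-find nodes
  min_pix <- min_area / pixel_size^2
  nodes <- list() # each: list(plane, label, pix = linear pixel ids)
  for (p in seq_len(np)) {
    m <- planes[[p]]
    for (lb in sort(unique(m[m > 0]))) {
      pix <- which(m == lb)
      if (length(pix) >= min_pix)
        nodes[[length(nodes) + 1]] <- list(plane = p, label = lb, pix = pix)
    }
  }
  nn <- length(nodes)
  if (nn == 0) {
    return(nuclei_seeds(array(0L, c(nx, ny, np)),
                        c(pixel_size, pixel_size, z_step), origin))
  }
  parent <- seq_len(nn)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  by_plane <- split(seq_len(nn), vapply(nodes, `[[`, 1L, "plane"))
  for (p in seq_len(np - 1)) {
    a_ids <- by_plane[[as.character(p)]]
    b_ids <- by_plane[[as.character(p + 1)]]
    if (is.null(a_ids) || is.null(b_ids)) next
    for (a in a_ids) for (b in b_ids) {
      shared <- length(intersect(nodes[[a]]$pix, nodes[[b]]$pix))
      smaller <- min(length(nodes[[a]]$pix), length(nodes[[b]]$pix))
      if (shared / smaller >= overlap_frac) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(nn), find, integer(1))
  comp <- split(seq_len(nn), roots)
  # drop components spanning too few planes, relabel survivors 1..K
  vol <- array(0L, c(nx, ny, np))
  k <- 0L
  for (cc in comp) {
    zspan <- length(unique(vapply(nodes[cc], `[[`, 1L, "plane")))
    if (zspan < min_z_extent) next
    k <- k + 1L
    for (i in cc) {
      sl <- vol[, , nodes[[i]]$plane]
      sl[nodes[[i]]$pix] <- k
      vol[, , nodes[[i]]$plane] <- sl
    }
  }
  nuclei_seeds(vol, c(pixel_size, pixel_size, z_step), origin)
}

#' Write segmentation outputs
#'
#' Emits plain-text artifacts: the label volume as a manifest (`volume.json`,
#' with dims/origin/pixel size) plus a long-format table of nonzero voxels
#' (`labels.tsv`); the cell-by-gene count matrix both as a wide delimited
#' table (`cells.tsv`, with cell ids, types and nucleus centroids) and as
#' MatrixMarket (`counts.mtx` + `cells.txt` + `genes.txt`); the per-spot
#' assignment (`spot_assignment.tsv`, cell 0 = background); and a run
#' manifest (`manifest.json`).
#'
#' @param state a segmentation state from [run_jsta()] or the watershed
#'   initializers.
#' @param spots the spot table that was segmented.
#' @param dir output directory (created if needed).
#' @param manifest optional named list of run metadata (config, seed,
#'   schedule) stored in `manifest.json`.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(state, spots, dir, manifest = list()) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) stopf("cannot write to '%s'", dir)
  panel <- attr(spots, "panel")

  dims <- dim(state$labels)
  idx <- which(state$labels > 0)
  ijk <- array_index(idx, dims)
  write.table(
    data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
               cell = state$labels[idx]),
    file.path(dir, "labels.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(dims = dims, origin = state$grid$origin,
         pixel_size = state$grid$pixel_size),
    file.path(dir, "volume.json"), auto_unbox = TRUE, digits = NA)

  assign <- spot_assignments(state, spots)
  write.table(data.frame(spot = seq_len(nrow(spots)), cell = assign),
              file.path(dir, "spot_assignment.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  E_c <- counts_from_segmentation(state, spots)
  cells <- data.frame(cell = as.integer(rownames(E_c)),
                      type = state$cell_type[rownames(E_c)])
  wide <- cbind(cells, as.data.frame(E_c))
  write.table(wide, file.path(dir, "cells.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  Matrix::writeMM(Matrix::Matrix(E_c, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(E_c), file.path(dir, "cells.txt"))
  writeLines(panel$names, file.path(dir, "genes.txt"))

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a label volume written by [write_outputs()]
#'
#' @param dir directory containing `volume.json` and `labels.tsv`.
#' @return 3D integer array of cell labels.
#' @export
read_labels_volume <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "volume.json"),
                              simplifyVector = TRUE)
  tab <- read.delim(file.path(dir, "labels.tsv"))
  vol <- array(0L, meta$dims)
  vol[cbind(tab$i, tab$j, tab$k)] <- as.integer(tab$cell)
  vol
}
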