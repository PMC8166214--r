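#' Build a regular 3D pixel grid over the data
#'
#' The grid spans the union bounding box of the spots and the nuclei
#' volume, padded by one pixel on every side, with the origin snapped to a
#' multiple of the pixel size so binning is deterministic.
#'
#' @param spots a `jsta_spots` table (may be NULL if nuclei given).
#' @param nuclei a [nuclei_seeds()] object (may be NULL if spots given).
#' @param pixel_size pixel edge in micrometers (2 is typical for empirical
#'   data, 1 for simulations).
#' @return a `jsta_grid`: `origin`, `pixel_size`, `dims`, and `centers()`
#'   accessors used internally.
#' @export
build_grid <- function(spots, nuclei, pixel_size) {
  if (pixel_size <= 0) stopf("pixel_size must be positive")
  lo <- c(Inf, Inf, Inf); hi <- c(-Inf, -Inf, -Inf)
  if (!is.null(spots) && nrow(spots) > 0) {
    sm <- as.matrix(spots[, c("x", "y", "z")])
    lo <- pmin(lo, apply(sm, 2, min))
    hi <- pmax(hi, apply(sm, 2, max))
  }
  if (!is.null(nuclei) && any(nuclei$labels > 0)) {
    ext <- dim(nuclei$labels) * nuclei$voxel_size
    lo <- pmin(lo, nuclei$origin)
    hi <- pmax(hi, nuclei$origin + ext)
  }
  if (!all(is.finite(lo))) stopf("need at least one spot or one nucleus")
  origin <- floor(lo / pixel_size) * pixel_size - pixel_size
  dims <- as.integer(ceiling((hi - origin) / pixel_size) + 1L)
  structure(list(origin = origin, pixel_size = pixel_size, dims = dims),
            class = "jsta_grid")
}

#' @export
print.jsta_grid <- function(x, ...) {
  cat(sprintf("<jsta_grid> %s pixels of %g um, origin (%s)\n",
              paste(x$dims, collapse = "x"), x$pixel_size,
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

# physical centers of all grid pixels, in linear-index order
grid_centers <- function(grid) {
  d <- grid$dims
  vox <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  voxel_center(vox, grid$origin, grid$pixel_size)
}

#' Per-pixel, per-gene K-nearest-neighbor density estimate
#'
#' For each pixel center and each gene, the density is K divided by the
#' volume of the ball reaching the K-th nearest spot of that gene:
#' `K / ((4/3) * pi * r^3)` with r in micrometers, giving spots per cubic
#' micrometer. Genes with fewer than K spots in the whole dataset get zero
#' density everywhere (a truncated-radius estimate there would be
#' unstable). If the K-th spot coincides with the pixel center (r = 0), r
#' is replaced by one tenth of the pixel size.
#'
#' @param spots a `jsta_spots` table.
#' @param grid a [build_grid()] result.
#' @param K neighbor count (default 5).
#' @param genes optional integer indices or names restricting the panel
#'   (e.g. the marker subset); columns are still indexed by the full panel.
#' @return matrix `n_pixels x length(genes)` of densities, columns named by
#'   gene.
#' @export
knn_density <- function(spots, grid, K = 5, genes = NULL) {
  if (K < 1) stopf("K must be at least 1")
  panel <- attr(spots, "panel")
  if (is.null(genes)) genes <- seq_along(panel$names)
  if (is.character(genes)) genes <- match(genes, panel$names)
  centers <- grid_centers(grid)
  n_p <- nrow(centers)
  E_p <- matrix(0, n_p, length(genes),
                dimnames = list(NULL, panel$names[genes]))
  coords <- as.matrix(spots[, c("x", "y", "z")])
  r0 <- grid$pixel_size / 10
  for (j in seq_along(genes)) {
    sel <- spots$gene == genes[j]
    if (sum(sel) < K) next
    r <- .cpp_kth_nn_dist(centers, coords[sel, , drop = FALSE], as.integer(K))
    r[r == 0] <- r0
    E_p[, j] <- K / ((4 / 3) * pi * r^3)
  }
  E_p
}
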