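#' Simulation parameters
#'
#' Defaults correspond to the reference simulation design: cell centers on
#' a jittered 3D grid over a 200 x 200 x 30 um volume with mean spacing
#' 4 um, per-cell capture radii between 5 and 7 um, removal of cells under
#' 30 pixels, two rounds of merging touching neighbors into irregular
#' shapes, 20-pixel nuclei, and 1 um pixels.
#'
#' @param extent volume in micrometers (X, Y, Z).
#' @param center_spacing mean distance between cell centers (um).
#' @param jitter_sd per-axis Gaussian jitter SD of the centers (um).
#' @param r_min,r_max bounds of each cell's capture radius (um); a pixel
#'   joins its nearest center only if within that center's radius.
#' @param min_cell_pixels cells with fewer pixels are removed.
#' @param merge_rounds rounds of merging pairs of touching cells.
#' @param nucleus_pixels target nucleus size in pixels.
#' @param pixel_size simulation pixel edge (um).
#' @param centering_weight fraction of a cell's spots drawn from the
#'   dilated nuclear region rather than uniformly (mild nuclear centering).
#' @param seed integer; fixes the full tissue draw.
#' @return list of validated parameters.
#' @export
sim_params <- function(extent = c(200, 200, 30), center_spacing = 4,
                       jitter_sd = 0.6, r_min = 5, r_max = 7,
                       min_cell_pixels = 30, merge_rounds = 2,
                       nucleus_pixels = 20, pixel_size = 1,
                       centering_weight = 0.25, seed = NULL) {
  stopifnot(length(extent) == 3, all(extent > 0), r_min < r_max,
            center_spacing > 0, pixel_size > 0, min_cell_pixels >= 1)
  if (any(extent < center_spacing))
    stopf("extent too small to host any cell center")
  as.list(environment())
}

# 6-connectivity offsets in voxel index space
FACE_OFFSETS <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                      c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))

# linear ids of in-bounds face neighbors for each of `lin` (list column-wise)
face_neighbors <- function(lin, dims) {
  ijk <- array_index(lin, dims)
  out <- vector("list", 6)
  for (o in seq_len(6)) {
    nb <- sweep(ijk, 2, FACE_OFFSETS[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    li <- rep(NA_integer_, length(lin))
    li[ok] <- linear_index(nb[ok, , drop = FALSE], dims)
    out[[o]] <- li
  }
  out
}

#' Generate a ground-truth cell map
#'
#' Places jittered cell centers, assigns pixels to their nearest center
#' within that center's capture radius, removes undersized cells, merges
#' touching neighbors for `merge_rounds` rounds, assigns each surviving
#' cell a type uniformly over the taxonomy, and grows a nucleus inside
#' each cell (border pixels removed).
#'
#' @param params from [sim_params()].
#' @param taxonomy a `jsta_taxonomy` supplying the type set.
#' @return list with `labels` (3D array of cell ids), `nuclei`
#'   ([nuclei_seeds()]), and `true_types` (named character).
#' @export
generate_cell_map <- function(params, taxonomy) {
  with_seed(params$seed, generate_cell_map_(params, taxonomy))
}

generate_cell_map_ <- function(params, taxonomy) {
  px <- params$pixel_size
  dims <- as.integer(ceiling(params$extent / px))
  ax <- lapply(1:3, function(d)
    seq(params$center_spacing / 2, params$extent[d], by = params$center_spacing))
  centers <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  centers <- centers + matrix(rnorm(length(centers), 0, params$jitter_sd),
                              ncol = 3)
  nc <- nrow(centers)
  radius <- runif(nc, params$r_min, params$r_max)

  vox <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  vxyz <- (vox - 0.5) * px
  nn <- .cpp_nearest_labeled(vxyz, centers, seq_len(nc))
  lab <- ifelse(nn$dist <= radius[nn$label], nn$label, 0L)
  labels <- array(as.integer(lab), dims)

  # drop undersized cells
  sizes <- tabulate(labels[labels > 0], nbins = nc)
  small <- which(sizes > 0 & sizes < params$min_cell_pixels)
  if (length(small)) labels[labels %in% small] <- 0L

  # merge touching neighbors
  for (round in seq_len(params$merge_rounds)) {
    adj <- label_adjacency(labels)
    alive <- sort(unique(labels[labels > 0]))
    merged <- logical(max(alive))
    for (c_id in sample(alive)) {
      if (merged[c_id]) next
      nbrs <- adj[[as.character(c_id)]]
      nbrs <- nbrs[!merged[nbrs]]
      if (!length(nbrs)) next
      partner <- if (length(nbrs) == 1) nbrs else sample(nbrs, 1)
      keep <- min(c_id, partner)
      labels[labels == max(c_id, partner)] <- keep
      merged[c(c_id, partner)] <- TRUE
    }
  }

  # relabel 1..K
  alive <- sort(unique(labels[labels > 0]))
  remap <- integer(max(alive))
  remap[alive] <- seq_along(alive)
  labels[labels > 0] <- remap[labels[labels > 0]]
  n_cells <- length(alive)
  if (n_cells == 0) stopf("no cells survived; enlarge the extent")

  true_types <- stats::setNames(
    sample(taxonomy$types, n_cells, replace = TRUE), seq_len(n_cells))

  nuc <- grow_nuclei(labels, params$nucleus_pixels)
  # a cell can lose its nucleus entirely to border removal; drop such cells
  lost <- setdiff(seq_len(n_cells), sort(unique(nuc[nuc > 0])))
  if (length(lost)) {
    labels[labels %in% lost] <- 0L
    nuc[nuc %in% lost] <- 0L
    keepers <- sort(unique(labels[labels > 0]))
    remap <- integer(n_cells)
    remap[keepers] <- seq_along(keepers)
    labels[labels > 0] <- remap[labels[labels > 0]]
    nuc[nuc > 0] <- remap[nuc[nuc > 0]]
    true_types <- stats::setNames(true_types[as.character(keepers)],
                                  seq_along(keepers))
  }
  list(labels = labels,
       nuclei = nuclei_seeds(nuc, rep(px, 3)),
       true_types = true_types)
}

# adjacency (6-connectivity) between distinct positive labels
label_adjacency <- function(labels) {
  dims <- dim(labels)
  pairs <- list()
  for (o in 1:3) {
    ia <- switch(o, seq_len(dims[1] - 1), seq_len(dims[1]), seq_len(dims[1]))
    a <- switch(o,
                labels[-dims[1], , , drop = FALSE],
                labels[, -dims[2], , drop = FALSE],
                labels[, , -dims[3], drop = FALSE])
    b <- switch(o,
                labels[-1, , , drop = FALSE],
                labels[, -1, , drop = FALSE],
                labels[, , -1, drop = FALSE])
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs[[length(pairs) + 1]] <- cbind(a[sel], b[sel])
  }
  if (!length(pairs)) return(list())
  pp <- unique(do.call(rbind, pairs))
  pp <- rbind(pp, pp[, 2:1])
  split(pp[, 2], as.character(pp[, 1])) |> lapply(unique)
}

# grow a nucleus of `n_pix` pixels inside each cell by random face-neighbor
# accretion from an interior seed, then remove nucleus pixels lying on the
# cell border
grow_nuclei <- function(labels, n_pix) {
  dims <- dim(labels)
  nuc <- array(0L, dims)
  cell_pix <- split(which(labels > 0), labels[labels > 0])
  for (cid_chr in names(cell_pix)) {
    cid <- as.integer(cid_chr)
    pix <- cell_pix[[cid_chr]]
    inside <- interior_mask(pix, labels, dims, cid)
    seed_pool <- if (any(inside)) pix[inside] else pix
    seed <- if (length(seed_pool) == 1) seed_pool else sample(seed_pool, 1)
    region <- seed
    in_cell <- logical(prod(dims))
    in_cell[pix] <- TRUE
    in_region <- logical(prod(dims))
    in_region[seed] <- TRUE
    while (length(region) < n_pix) {
      nbs <- unlist(face_neighbors(region, dims))
      nbs <- nbs[!is.na(nbs)]
      cand <- unique(nbs[in_cell[nbs] & !in_region[nbs]])
      if (!length(cand)) break
      add <- if (length(cand) == 1) cand else sample(cand, 1)
      region <- c(region, add)
      in_region[add] <- TRUE
    }
    keep <- region[interior_mask(region, labels, dims, cid)]
    nuc[keep] <- cid
  }
  nuc
}

# TRUE for pixels of `pix` whose face neighbors all stay inside cell `cid`
interior_mask <- function(pix, labels, dims, cid) {
  nbs <- face_neighbors(pix, dims)
  ok <- rep(TRUE, length(pix))
  for (o in seq_len(6)) {
    li <- nbs[[o]]
    out <- is.na(li)
    ok <- ok & !out & ifelse(out, FALSE, labels[ifelse(out, 1L, li)] == cid)
  }
  ok
}

#' Sample one cell's expression profile
#'
#' Draws a gene count vector from the type's multivariate Gaussian, rounds
#' to integers and clamps negatives to zero. A non-positive-semidefinite
#' covariance is repaired by clipping negative eigenvalues at zero, with a
#' warning.
#'
#' @param taxonomy a `jsta_taxonomy`.
#' @param type_id type name (or index).
#' @return length-m non-negative integer vector.
#' @export
sample_cell_expression <- function(taxonomy, type_id) {
  if (is.numeric(type_id)) type_id <- taxonomy$types[type_id]
  mu <- taxonomy$mu[type_id, ]
  sig <- taxonomy$sigma[[type_id]]
  key <- paste0(".chol_", type_id)
  fac <- attr(taxonomy, key)
  if (is.null(fac)) {
    eg <- eigen(sig, symmetric = TRUE)
    if (min(eg$values) < -1e-8 * max(abs(eg$values)))
      warnf("covariance of type '%s' not PSD; clipping eigenvalues at 0", type_id)
    vals <- pmax(eg$values, 0)
    fac <- eg$vectors %*% (sqrt(vals) * t(eg$vectors))
  }
  z <- rnorm(length(mu))
  x <- round(mu + as.numeric(fac %*% z))
  as.integer(pmax(x, 0))
}

#' Place mRNA spots inside cells
#'
#' For each cell and gene, emits the counted number of spots at uniformly
#' chosen pixels of the cell, except that a fraction `centering_weight` is
#' drawn from the one-pixel dilation of the nucleus (mild nuclear
#' centering). Spot coordinates are the pixel center plus a uniform
#' sub-pixel offset; the generating cell is recorded as `true_cell`.
#'
#' @param labels 3D cell-id array.
#' @param nuclei [nuclei_seeds()] on the same frame.
#' @param counts_per_cell cells x genes integer matrix, rownames = cell ids.
#' @param panel [gene_panel()] naming the genes (columns).
#' @param centering_weight fraction of nucleus-biased spots (default 0.25).
#' @param pixel_size pixel edge in micrometers.
#' @return a `jsta_spots` table with `true_cell` filled.
#' @export
place_spots <- function(labels, nuclei, counts_per_cell, panel,
                        centering_weight = 0.25, pixel_size = 1) {
  dims <- dim(labels)
  m <- ncol(counts_per_cell)
  stopifnot(m == length(panel$names))
  cell_pix <- split(which(labels > 0), labels[labels > 0])
  res_pix <- integer(0); res_gene <- integer(0); res_cell <- integer(0)
  for (cid_chr in rownames(counts_per_cell)) {
    pix <- cell_pix[[cid_chr]]
    stopifnot(length(pix) > 0)
    cid <- as.integer(cid_chr)
    counts <- counts_per_cell[cid_chr, ]
    total <- sum(counts)
    if (total == 0) next
    nuc_pix <- which(nuclei$labels == cid)
    nb <- unlist(face_neighbors(nuc_pix, dims))
    dil <- intersect(unique(c(nuc_pix, nb[!is.na(nb)])), pix)
    if (!length(dil)) dil <- pix
    use_nuc <- runif(total) < centering_weight
    chosen <- integer(total)
    if (any(use_nuc))
      chosen[use_nuc] <- dil[sample.int(length(dil), sum(use_nuc), replace = TRUE)]
    if (any(!use_nuc))
      chosen[!use_nuc] <- pix[sample.int(length(pix), sum(!use_nuc), replace = TRUE)]
    res_pix <- c(res_pix, chosen)
    res_gene <- c(res_gene, rep(seq_len(m), counts))
    res_cell <- c(res_cell, rep(cid, total))
  }
  ijk <- array_index(res_pix, dims)
  xyz <- (ijk - 1) * pixel_size +
    matrix(runif(3 * length(res_pix), 0, pixel_size), ncol = 3)
  spot_table(xyz[, 1], xyz[, 2], xyz[, 3], res_gene, panel,
             true_cell = res_cell)
}

#' Select marker genes by random-forest importance
#'
#' Fits a 100-tree random-forest type classifier on the reference and
#' returns the top-n genes by impurity importance.
#'
#' @param E_ref cells x genes matrix (columns named).
#' @param T_ref per-cell type labels.
#' @param n number of genes to keep.
#' @param seed integer for a deterministic forest.
#' @param num_trees forest size (default 100).
#' @return character vector of n gene names, ordered by importance.
#' @export
select_marker_genes <- function(E_ref, T_ref, n, seed = 1, num_trees = 100) {
  if (n < 1) stopf("n must be at least 1")
  if (n > ncol(E_ref)) stopf("n exceeds the number of genes")
  df <- as.data.frame(as.matrix(E_ref))
  if (is.null(colnames(E_ref))) colnames(df) <- paste0("g", seq_len(ncol(df)))
  df$.type <- factor(T_ref)
  fit <- ranger::ranger(.type ~ ., data = df, num.trees = num_trees,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  names(imp)[seq_len(n)]
}

#' Simulate a full ground-truth tissue
#'
#' Generates the cell map, draws each cell's expression from its type's
#' Gaussian, and places spots — the complete synthetic observable plus
#' ground truth for evaluating segmentation.
#'
#' @param taxonomy a `jsta_taxonomy`.
#' @param params from [sim_params()] (its `seed` fixes the entire draw).
#' @return a `jsta_truth` object: `labels`, `nuclei`, `true_types`, `spots`
#'   (with true_cell), `counts_true` (cells x genes), `panel`, `taxonomy`,
#'   `params`.
#' @export
simulate_tissue <- function(taxonomy, params = sim_params()) {
  with_seed(params$seed, {
    map <- generate_cell_map_(params, taxonomy)
    n_cells <- length(map$true_types)
    panel <- gene_panel(colnames(taxonomy$mu))
    counts <- t(vapply(seq_len(n_cells), function(c_id)
      sample_cell_expression(taxonomy, map$true_types[[c_id]]),
      numeric(taxonomy$m)))
    rownames(counts) <- seq_len(n_cells)
    colnames(counts) <- panel$names
    spots <- place_spots(map$labels, map$nuclei, counts, panel,
                         centering_weight = params$centering_weight,
                         pixel_size = params$pixel_size)
    structure(list(labels = map$labels, nuclei = map$nuclei,
                   true_types = map$true_types, spots = spots,
                   counts_true = counts, panel = panel,
                   taxonomy = taxonomy, params = params),
              class = "jsta_truth")
  })
}

#' @export
print.jsta_truth <- function(x, ...) {
  cat(sprintf("<jsta_truth> %d cells, %d spots, %s um volume\n",
              length(x$true_types), nrow(x$spots),
              paste(x$params$extent, collapse = "x")))
  invisible(x)
}
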