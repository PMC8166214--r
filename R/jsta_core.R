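#' Reassignment parameters for the EM loop
#'
#' The `"empirical"` preset is the schedule used on real tissue (6 training
#' rounds x 10 reassignment iterations, probability floor 0.05); the
#' `"simulation"` preset uses 5 x 5 and floor 0.01.
#'
#' @param preset `"empirical"` or `"simulation"`.
#' @param d automatic-assignment distance threshold in micrometers; pixels
#'   within `d` of a candidate nucleus are (effectively) assigned to it. It
#'   defaults to the watershed initialization radius of 2 um.
#' @param prob_floor probabilities below this are zeroed after
#'   renormalization.
#' @param anneal_rate per-iteration boost of the maximum probability; the
#'   max entry is multiplied by (1 + iteration * anneal_rate).
#' @param n_train_rounds pixel-classifier (re)training rounds.
#' @param n_reassign_iters border reassignment iterations per round.
#' @param pixel_sample_frac fraction of assigned pixels sampled for
#'   training.
#' @param retype_each_iteration re-run the cell classifier after every
#'   reassignment iteration (default FALSE: cells are typed once).
#' @param decay distance-decay form of the probability rescaling; the
#'   rational form halves the probability at r - d = 5d. The exponential
#'   alternative `2^-((r-d)/(5d))` shares that halving point.
#' @param seed integer driving every stochastic step of the loop.
#' @return list of validated parameters.
#' @export
reassignment_params <- function(preset = c("empirical", "simulation"),
                                d = 2, prob_floor = NULL, anneal_rate = 0.05,
                                n_train_rounds = NULL, n_reassign_iters = NULL,
                                pixel_sample_frac = 0.10,
                                retype_each_iteration = FALSE,
                                decay = c("rational", "exponential"),
                                seed = 1) {
  preset <- match.arg(preset)
  decay <- match.arg(decay)
  if (is.null(prob_floor)) prob_floor <- if (preset == "empirical") 0.05 else 0.01
  if (is.null(n_train_rounds)) n_train_rounds <- if (preset == "empirical") 6 else 5
  if (is.null(n_reassign_iters)) n_reassign_iters <- if (preset == "empirical") 10 else 5
  stopifnot(d > 0, prob_floor > 0, prob_floor < 1, anneal_rate >= 0,
            n_train_rounds >= 1, n_reassign_iters >= 1,
            pixel_sample_frac > 0, pixel_sample_frac <= 1)
  list(preset = preset, d = d, prob_floor = prob_floor,
       anneal_rate = anneal_rate, n_train_rounds = n_train_rounds,
       n_reassign_iters = n_reassign_iters,
       pixel_sample_frac = pixel_sample_frac,
       retype_each_iteration = retype_each_iteration,
       decay = decay, seed = seed)
}

# segmentation state constructor; nucleus geometry is precomputed once
make_state <- function(labels, grid, nuclei, cell_type = NULL) {
  cell_ids <- sort(unique(nuclei$labels[nuclei$labels > 0]))
  nuc_idx <- which(nuclei$labels > 0)
  nuc_ijk <- array_index(nuc_idx, dim(nuclei$labels))
  nuc_xyz <- voxel_center_aniso(nuc_ijk, nuclei$origin, nuclei$voxel_size)
  nuc_cell <- nuclei$labels[nuc_idx]
  ord <- order(nuc_cell)
  nuc_xyz <- nuc_xyz[ord, , drop = FALSE]
  nuc_cell <- nuc_cell[ord]
  runs <- rle(nuc_cell)
  start <- stats::setNames(cumsum(c(1L, head(runs$lengths, -1))), runs$values)
  end <- stats::setNames(cumsum(runs$lengths), runs$values)

  # grid pixels hosting nucleus voxels are pinned to their cell
  gi <- coord_to_voxel(nuc_xyz, grid$origin, grid$pixel_size)
  lin <- linear_index(gi, grid$dims)
  nucleus_pixel <- integer(prod(grid$dims))
  nucleus_pixel[lin] <- nuc_cell
  labels[lin] <- nuc_cell

  structure(list(labels = labels, grid = grid, nuclei = nuclei,
                 cell_ids = cell_ids,
                 cell_type = stats::setNames(cell_type %||%
                                               rep(NA_character_, length(cell_ids)),
                                             cell_ids),
                 nucleus_pixel = nucleus_pixel,
                 nuc_xyz = nuc_xyz, nuc_start = start, nuc_end = end,
                 iteration = 0L, diagnostics = NULL),
            class = "jsta_state")
}

#' @export
print.jsta_state <- function(x, ...) {
  cat(sprintf("<jsta_state> %d cells, %d/%d pixels assigned, iteration %d\n",
              length(x$cell_ids), sum(x$labels > 0), length(x$labels),
              x$iteration))
  invisible(x)
}

#' Initialize segmentation by distance-capped watershed from the nuclei
#'
#' Performs the watershed of the Euclidean distance transform from the
#' nuclei: every pixel within `max_dist` of a nucleus joins the nearest
#' nucleus (ties to the lowest cell id); pixels farther away stay
#' background.
#'
#' @param grid a [build_grid()] result.
#' @param nuclei [nuclei_seeds()].
#' @param max_dist assignment cap in micrometers (default 2).
#' @return a `jsta_state`.
#' @export
watershed_initialize <- function(grid, nuclei, max_dist = 2) {
  if (!any(nuclei$labels > 0)) stopf("no nuclei to seed from")
  nuc_idx <- which(nuclei$labels > 0)
  nuc_ijk <- array_index(nuc_idx, dim(nuclei$labels))
  nuc_xyz <- voxel_center_aniso(nuc_ijk, nuclei$origin, nuclei$voxel_size)
  centers <- grid_centers(grid)
  nn <- .cpp_nearest_labeled(centers, nuc_xyz, nuclei$labels[nuc_idx])
  labels <- array(ifelse(nn$dist <= max_dist, nn$label, 0L), grid$dims)
  make_state(labels, grid, nuclei)
}

#' Density-based watershed baseline segmentation
#'
#' The comparison baseline: per-pixel total density (sum over genes) is
#' log2-transformed, pixels with transformed value below 1 are masked out,
#' and a marker-based compactness-weighted watershed (compactness 10) runs
#' on the negated masked density from the nuclei seeds, with a one-pixel
#' watershed line separating touching cells.
#'
#' @param grid a [build_grid()] result.
#' @param nuclei [nuclei_seeds()].
#' @param E_p density matrix from [knn_density()] (any gene subset; summed).
#' @param compactness compactness weight (default 10).
#' @return a `jsta_state`.
#' @export
watershed_baseline <- function(grid, nuclei, E_p, compactness = 10) {
  total <- rowSums(E_p)
  v <- log2(pmax(total, .Machine$double.xmin))
  mask <- v >= 1

  # seed volume: nucleus voxels binned onto the grid
  nuc_idx <- which(nuclei$labels > 0)
  nuc_ijk <- array_index(nuc_idx, dim(nuclei$labels))
  nuc_xyz <- voxel_center_aniso(nuc_ijk, nuclei$origin, nuclei$voxel_size)
  gi <- coord_to_voxel(nuc_xyz, grid$origin, grid$pixel_size)
  seeds <- integer(prod(grid$dims))
  seeds[linear_index(gi, grid$dims)] <- nuclei$labels[nuc_idx]
  if (!any(mask) && !any(seeds > 0)) stopf("all pixels masked; no signal")
  mask[seeds > 0] <- TRUE

  lab <- .cpp_compact_watershed(grid$dims, -v, array(seeds, grid$dims),
                                array(mask, grid$dims), compactness,
                                rep(grid$pixel_size, 3), TRUE)
  make_state(array(lab, grid$dims), grid, nuclei)
}

# 26-neighbor label matrix: n_pixels x 26, -1 = outside the volume
neighbor_labels <- function(labels) {
  dims <- dim(labels)
  P <- array(-1L, dims + 2L)
  P[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- labels
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  out <- matrix(-1L, length(labels), nrow(offs))
  for (o in seq_len(nrow(offs))) {
    sl <- P[(2:(dims[1] + 1)) + offs[o, 1],
            (2:(dims[2] + 1)) + offs[o, 2],
            (2:(dims[3] + 1)) + offs[o, 3]]
    out[, o] <- sl
  }
  out
}

#' Identify border pixels eligible for reassignment
#'
#' A labeled pixel is a border pixel when it touches a differently typed
#' cell or background AND at least 5 of its 26-connected neighbors are from
#' such a foreign region AND at least 2 are from its own cell. Interfaces
#' between two cells of the same type are never borders (they stay as the
#' initial watershed left them). A background pixel is an accretion
#' candidate for any adjacent cell contributing at least 5 of its
#' neighbors, provided at least 2 neighbors are background. Nucleus-bearing
#' pixels are never borders.
#'
#' @param state a `jsta_state` with cell types assigned.
#' @return list with `lin` (linear pixel indices of the border pixels),
#'   `own` (current label per border pixel, 0 = background), and the
#'   candidate (pixel, cell) pairs as parallel vectors `pair_pt` (index
#'   into `lin`) and `pair_cell` (candidate cell id, excluding the pixel's
#'   own cell).
#' @export
border_pixels <- function(state) {
  labels <- state$labels
  nb <- neighbor_labels(labels)
  cells <- as.integer(names(state$cell_type))
  type_int <- match(state$cell_type, sort(unique(state$cell_type)))
  maxlab <- max(cells)
  type_lut <- integer(maxlab) # 1-based cell id -> type index
  type_lut[cells] <- type_int
  lab_vec <- as.integer(labels)

  lin <- integer(0); own <- integer(0)
  pair_pt <- integer(0); pair_cell <- integer(0)

  ## labeled border pixels (nucleus-bearing pixels are pinned)
  lab_pix <- which(lab_vec > 0 & state$nucleus_pixel == 0L)
  if (length(lab_pix)) {
    nbp <- nb[lab_pix, , drop = FALSE]
    ownp <- lab_vec[lab_pix]
    own_type <- type_lut[ownp]
    n_same <- rowSums(nbp == ownp)
    nb_type <- matrix(0L, nrow(nbp), ncol(nbp))
    pos <- nbp > 0L
    nb_type[pos] <- type_lut[nbp[pos]]
    foreign <- (nbp == 0L) | (pos & nb_type != own_type)
    n_foreign <- rowSums(foreign)
    sel <- which(n_foreign >= 5 & n_same >= 2)
    if (length(sel)) {
      lin <- lab_pix[sel]
      own <- ownp[sel]
      # candidate cells: differently typed neighbors, deduplicated
      nc <- ncol(nbp)
      long_pt <- rep(seq_along(sel), nc)
      long_cell <- as.integer(nbp[sel, , drop = FALSE])
      ot <- own_type[sel]
      keep <- long_cell > 0L & type_lut[pmax(long_cell, 1L)] != ot[long_pt]
      long_pt <- long_pt[keep]; long_cell <- long_cell[keep]
      key <- (long_pt - 1) * (maxlab + 1) + long_cell
      dup <- duplicated(key)
      pair_pt <- long_pt[!dup]
      pair_cell <- long_cell[!dup]
    }
  }

  ## background accretion candidates: >= 5 neighbors from the target cell,
  ## >= 2 background neighbors
  bg_pix <- which(lab_vec == 0L)
  if (length(bg_pix)) {
    nbp <- nb[bg_pix, , drop = FALSE]
    n_bg <- rowSums(nbp == 0L)
    rows <- which(n_bg >= 2 & rowSums(nbp > 0L) >= 5)
    if (length(rows)) {
      nc <- ncol(nbp)
      long_pt <- rep(rows, nc)
      long_cell <- as.integer(nbp[rows, , drop = FALSE])
      keep <- long_cell > 0L
      long_pt <- long_pt[keep]; long_cell <- long_cell[keep]
      key <- (long_pt - 1) * (maxlab + 1) + long_cell
      cnt <- table(key)
      ok_keys <- as.numeric(names(cnt)[cnt >= 5])
      if (length(ok_keys)) {
        bp <- as.integer(ok_keys %/% (maxlab + 1)) + 1L
        bc <- as.integer(ok_keys %% (maxlab + 1))
        upix <- sort(unique(bp))
        off <- length(lin)
        lin <- c(lin, bg_pix[upix])
        own <- c(own, rep(0L, length(upix)))
        pair_pt <- c(pair_pt, off + match(bp, upix))
        pair_cell <- c(pair_cell, bc)
      }
    }
  }
  list(lin = lin, own = own, pair_pt = pair_pt, pair_cell = pair_cell)
}

# vectorized form of rescale_pixel_probabilities over rows:
# Q (n x k) classifier probabilities, R (n x k) per-type distance to the
# nearest candidate nucleus (Inf = no candidate of that type)
rescale_rows <- function(Q, R, d, prob_floor, decay = "rational") {
  fac <- matrix(0, nrow(Q), ncol(Q))
  far <- is.finite(R) & R >= d
  fac[far] <- if (decay == "rational") {
    (5 * d) / (2 * (R[far] - d))
  } else {
    2^(-(R[far] - d) / (5 * d))
  }
  QP <- pmin(Q * fac, 10)
  QP[is.finite(R) & R < d] <- 10
  QP[!is.finite(R)] <- 0
  rs <- rowSums(QP)
  bg <- rs == 0
  QN <- QP / ifelse(rs == 0, 1, rs)
  QN[QN < prob_floor] <- 0
  rs2 <- rowSums(QN)
  bg <- bg | rs2 == 0
  QN <- QN / ifelse(rs2 == 0, 1, rs2)
  list(Q = QN, background = bg)
}

# vectorized annealed multinomial draw per row (inverse-CDF sampling)
anneal_sample_rows <- function(Q, iteration, anneal_rate) {
  n <- nrow(Q); k <- ncol(Q)
  mx <- max.col(Q, ties.method = "first")
  Q[cbind(seq_len(n), mx)] <- Q[cbind(seq_len(n), mx)] * (1 + iteration * anneal_rate)
  Q <- Q / rowSums(Q)
  cs <- Q
  if (k > 1) for (j in 2:k) cs[, j] <- cs[, j - 1] + Q[, j]
  u <- runif(n)
  1L + rowSums(cs < u)
}

#' Distance-rescale a pixel's type probabilities
#'
#' Applies the spatial prior to a pixel-classifier probability row: a type
#' whose nearest candidate nucleus is within `d` gets the dominating value
#' 10; otherwise the probability is scaled by `5d / (2(r - d))` (capped at
#' 10), which halves it at r - d = 5d. Types not represented among the
#' pixel's neighboring cells are zeroed. After renormalization, entries
#' below `prob_floor` are zeroed and the row renormalized again; an
#' all-zero row flags the pixel as background.
#'
#' @param q probability row over the k types.
#' @param r_to_nearest per-type distance (um) to the nearest candidate
#'   nucleus of that type; `Inf` (or NA) for types with no candidate.
#' @param d automatic-assignment distance (um).
#' @param prob_floor minimum retained probability.
#' @param decay `"rational"` (default) or `"exponential"`.
#' @return list with `q` (updated probability row) and `background`
#'   (TRUE when every type was eliminated).
#' @export
rescale_pixel_probabilities <- function(q, r_to_nearest, d = 2,
                                        prob_floor = 0.05,
                                        decay = c("rational", "exponential")) {
  decay <- match.arg(decay)
  r <- r_to_nearest
  if (any(r[is.finite(r)] < 0)) stopf("distances must be non-negative")
  r[is.na(r)] <- Inf
  qp <- numeric(length(q))
  near <- is.finite(r) & r < d
  far <- is.finite(r) & r >= d
  qp[near] <- 10
  if (any(far)) {
    fac <- if (decay == "rational") {
      (5 * d) / (2 * (r[far] - d))
    } else {
      2^(-(r[far] - d) / (5 * d))
    }
    qp[far] <- pmin(q[far] * fac, 10)
  }
  if (sum(qp) == 0) return(list(q = qp, background = TRUE))
  qn <- qp / sum(qp)
  qn[qn < prob_floor] <- 0
  if (sum(qn) == 0) return(list(q = qn, background = TRUE))
  list(q = qn / sum(qn), background = FALSE)
}

#' Annealed multinomial draw of a pixel's type
#'
#' Multiplies the maximum entry by `(1 + iteration * anneal_rate)`,
#' renormalizes and samples: early iterations explore, late iterations
#' exploit the argmax.
#'
#' @param q probability row (non-negative, summing to 1).
#' @param iteration global reassignment iteration (0-based).
#' @param anneal_rate boost per iteration (default 0.05).
#' @return sampled type index (1-based).
#' @export
anneal_and_sample <- function(q, iteration, anneal_rate = 0.05) {
  j <- which.max(q)
  q[j] <- q[j] * (1 + iteration * anneal_rate)
  q <- q / sum(q)
  sample.int(length(q), 1, prob = q)
}

#' Assign spots to cells through the current label map
#'
#' @param state a `jsta_state`.
#' @param spots a `jsta_spots` table.
#' @return integer vector of cell ids per spot (0 = background); spots
#'   falling outside the grid count as background with a warning.
#' @export
spot_assignments <- function(state, spots) {
  g <- state$grid
  ijk <- coord_to_voxel(as.matrix(spots[, c("x", "y", "z")]), g$origin,
                        g$pixel_size)
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= g$dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= g$dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= g$dims[3]
  if (any(!inside)) warnf("%d spot(s) outside the grid counted as background",
                          sum(!inside))
  out <- integer(nrow(spots))
  out[inside] <- state$labels[linear_index(ijk[inside, , drop = FALSE], g$dims)]
  out
}

#' Cell-by-gene counts from the current segmentation
#'
#' @param state a `jsta_state`.
#' @param spots a `jsta_spots` table.
#' @param genes optional gene subset (indices or names).
#' @return integer matrix cells x genes (rownames = cell ids, including
#'   zero-count cells). Background spots are excluded.
#' @export
counts_from_segmentation <- function(state, spots, genes = NULL) {
  panel <- attr(spots, "panel")
  if (is.null(genes)) genes <- seq_along(panel$names)
  if (is.character(genes)) genes <- match(genes, panel$names)
  assign <- spot_assignments(state, spots)
  keep <- assign > 0 & spots$gene %in% genes
  E_c <- matrix(0L, length(state$cell_ids), length(genes),
                dimnames = list(state$cell_ids, panel$names[genes]))
  if (any(keep)) {
    tab <- table(factor(assign[keep], levels = state$cell_ids),
                 factor(spots$gene[keep], levels = genes))
    E_c[] <- as.integer(tab)
  }
  E_c
}

# distance from each (pixel, candidate-cell) pair to that cell's nucleus
pair_nucleus_dist <- function(state, pix_xyz, pair_pt, pair_cell) {
  key <- as.character(pair_cell)
  .cpp_pair_min_dist(pix_xyz, as.integer(pair_pt),
                     match(key, names(state$nuc_start)),
                     state$nuc_xyz,
                     as.integer(state$nuc_start),
                     as.integer(state$nuc_end))
}

#' Run the full JSTA segmentation
#'
#' The joint EM loop: (1) build the density grid; (2) initialize the label
#' map by distance-capped watershed from the nuclei; (3) type the initial
#' cells with the reference-trained cell classifier; (4) for each training
#' round, (re)train the pixel classifier on a sample of assigned pixels
#' (warm-started after the first round), then run several iterations of
#' border-pixel reassignment: classifier probabilities are rescaled by
#' nucleus distance, restricted to neighboring types, annealed toward the
#' argmax, and sampled; (5) recount the full gene panel and re-type the
#' final cells.
#'
#' Degenerate case: if the initial cells all receive the same type, no
#' pixel classifier can be trained and the initial watershed state is
#' returned unchanged (with a diagnostic note).
#'
#' @param spots a `jsta_spots` table.
#' @param nuclei [nuclei_seeds()].
#' @param reference a `jsta_taxonomy` carrying reference cells (`E_ref`,
#'   `T_ref`), used to train the cell classifier — or a pre-trained
#'   `jsta_cell_classifier`.
#' @param markers marker gene subset used for densities and classification
#'   (names or indices; default: the panel's marker mask).
#' @param pixel_size grid pixel edge in um (2 empirical, 1 simulation).
#' @param K density neighbor count (default 5).
#' @param params a [reassignment_params()] list.
#' @param cell_cfg optional [train_config()] for the cell classifier.
#' @return the final `jsta_state`; `$counts` holds the full-panel cell
#'   counts, `$P_c` the cell type probabilities, `$diagnostics` a
#'   per-iteration data.frame (border pixels, flips, mean max pixel
#'   probability), `$E_p` the density matrix and `$pixel_classifier` the
#'   final classifier.
#' @export
run_jsta <- function(spots, nuclei, reference, markers = NULL,
                     pixel_size = 1, K = 5,
                     params = reassignment_params("simulation"),
                     cell_cfg = NULL) {
  panel <- attr(spots, "panel")
  if (is.null(markers)) markers <- which(panel$marker_mask)
  if (is.character(markers)) markers <- match(markers, panel$names)
  if (!length(markers)) stopf("marker subset is empty")

  grid <- build_grid(spots, nuclei, pixel_size)
  E_p <- knn_density(spots, grid, K = K, genes = markers)
  state <- watershed_initialize(grid, nuclei, max_dist = params$d)

  ## cell classifier
  clf <- if (inherits(reference, "jsta_cell_classifier")) {
    reference
  } else {
    if (is.null(reference$E_ref)) stopf("reference taxonomy carries no cells; use sample_reference_cells()")
    cfg <- cell_cfg %||% train_config(c(5e-3, 5e-4), c(20, 20), split = 0.75,
                                      seed = params$seed)
    train_cell_classifier(
      harmonize_expression(reference$E_ref[, markers, drop = FALSE]),
      reference$T_ref, cfg)
  }

  retype <- function(state) {
    E_c <- counts_from_segmentation(state, spots, genes = markers)
    res <- classify_cells(clf, harmonize_expression(E_c))
    state$cell_type[] <- res$T_c
    state$P_c <- res$P_c
    state
  }
  state <- retype(state)

  if (length(unique(state$cell_type)) < 2) {
    state$counts <- counts_from_segmentation(state, spots)
    state$diagnostics <- data.frame()
    state$note <- "single cell type; EM skipped, watershed boundaries kept"
    return(state)
  }

  type_levels <- clf$types
  centers <- grid_centers(grid)
  diagnostics <- data.frame()
  pixel_clf <- NULL
  global_iter <- 0L

  with_seed(params$seed, {
    for (round_t in seq_len(params$n_train_rounds)) {
      assigned <- which(as.integer(state$labels) > 0)
      n_samp <- max(2 * length(type_levels),
                    round(params$pixel_sample_frac * length(assigned)))
      samp <- sample(assigned, min(n_samp, length(assigned)))
      samp_types <- state$cell_type[as.character(state$labels[samp])]
      if (length(unique(samp_types)) < 2) next
      pixel_clf <- train_pixel_classifier(
        E_p[samp, , drop = FALSE], samp_types, types = type_levels,
        warm_start = pixel_clf)

      for (iter in seq_len(params$n_reassign_iters)) {
        bp <- border_pixels(state)
        n_b <- length(bp$lin)
        if (n_b == 0) {
          diagnostics <- rbind(diagnostics,
                               data.frame(round = round_t, iteration = global_iter,
                                          n_border = 0L, flips = 0L,
                                          mean_max_prob = NA_real_))
          global_iter <- global_iter + 1L
          next
        }
        Q <- pixel_type_probabilities(pixel_clf, E_p[bp$lin, , drop = FALSE])

        ## candidate (pixel, cell) pairs: foreign candidates plus own cell
        lab_rows <- which(bp$own > 0)
        pair_pt <- c(bp$pair_pt, lab_rows)
        pair_cell <- c(bp$pair_cell, bp$own[lab_rows])
        pix_xyz <- centers[bp$lin, , drop = FALSE]
        pr <- pair_nucleus_dist(state, pix_xyz, pair_pt, pair_cell)
        pair_type <- match(state$cell_type[as.character(pair_cell)], type_levels)

        # per (pixel, type): distance to and id of the nearest candidate cell
        k <- length(type_levels)
        R <- matrix(Inf, n_b, k)
        C <- matrix(NA_integer_, n_b, k)
        ord <- order(pr, pair_cell) # nearest first; id breaks exact ties
        key <- (pair_pt - 1) * k + pair_type
        first <- ord[!duplicated(key[ord])]
        R[cbind(pair_pt[first], pair_type[first])] <- pr[first]
        C[cbind(pair_pt[first], pair_type[first])] <- pair_cell[first]

        rs <- rescale_rows(Q, R, d = params$d, prob_floor = params$prob_floor,
                           decay = params$decay)
        t_idx <- anneal_sample_rows(rs$Q, global_iter,
                                    anneal_rate = params$anneal_rate)
        t_idx[is.na(t_idx)] <- 1L # background rows; overwritten below
        new_label <- C[cbind(seq_len(n_b), pmin(t_idx, k))]
        new_label[rs$background] <- 0L
        max_prob <- apply(Q, 1, max)
        flips <- sum(new_label != bp$own)
        state$labels[bp$lin] <- new_label
        diagnostics <- rbind(diagnostics,
                             data.frame(round = round_t, iteration = global_iter,
                                        n_border = n_b, flips = flips,
                                        mean_max_prob = mean(max_prob)))
        global_iter <- global_iter + 1L
        if (params$retype_each_iteration) state <- retype(state)
        if (flips < 0.001 * n_b) break
      }
    }
  })

  state$iteration <- global_iter
  state$diagnostics <- diagnostics
  state$pixel_classifier <- pixel_clf
  state$E_p <- E_p
  state <- retype(state)
  state$counts <- counts_from_segmentation(state, spots)
  state
}
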