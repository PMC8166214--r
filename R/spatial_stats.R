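#' Taxonomy-aware mRNA assignment accuracy
#'
#' For each predicted cell, the fraction of its assigned spots whose true
#' source is that cell — or a touching neighboring cell whose true type
#' falls in the same group at the evaluated granularity (misassignment
#' between same-group neighbors is not penalized, matching the method's
#' type-driven borders). The report is the mean over cells, per dendrogram
#' cut height.
#'
#' @param pred a `jsta_state` (predicted segmentation; its cell ids are the
#'   nucleus ids, so they match the simulator's true cell ids).
#' @param truth a `jsta_truth` from [simulate_tissue()].
#' @param heights dendrogram cut heights to sweep (default 0 to 0.8 by
#'   0.05).
#' @return list with `heights`, `k_groups`, `mean_accuracy` (per height),
#'   `per_cell` (cells x heights matrix), and `n_empty` (predicted cells
#'   with no spots, excluded from the mean).
#' @export
assignment_accuracy <- function(pred, truth, heights = seq(0, 0.8, by = 0.05)) {
  assign <- spot_assignments(pred, truth$spots)
  true_cell <- truth$spots$true_cell
  keep <- assign > 0
  pc <- assign[keep]
  tc <- true_cell[keep]

  adj <- label_adjacency(truth$labels)
  maxlab <- max(c(pc, tc, 1L))
  adj_keys <- unlist(lapply(names(adj), function(a)
    as.numeric(a) * (maxlab + 1) + adj[[a]]), use.names = FALSE)
  exact <- pc == tc
  near <- !exact & (as.numeric(pc) * (maxlab + 1) + tc) %in% adj_keys
  types <- truth$true_types

  cells_with_spots <- sort(unique(pc))
  n_empty <- length(setdiff(pred$cell_ids, cells_with_spots))

  per_cell <- matrix(NA_real_, length(cells_with_spots), length(heights),
                     dimnames = list(cells_with_spots, signif(heights, 3)))
  k_groups <- integer(length(heights))
  fcell <- factor(pc, levels = cells_with_spots)
  for (h in seq_along(heights)) {
    grouping <- granularity_grouping(truth$taxonomy, heights[h])
    k_groups[h] <- attr(grouping, "k_groups")
    g_pred <- grouping[types[as.character(pc)]]
    g_true <- grouping[types[as.character(tc)]]
    correct <- exact | (near & g_pred == g_true)
    per_cell[, h] <- tapply(correct, fcell, mean)
  }
  list(heights = heights, k_groups = k_groups,
       mean_accuracy = colMeans(per_cell),
       per_cell = per_cell, n_empty = n_empty)
}

#' Per-type expression correlation between segmentation and reference
#'
#' Averages expression per gene within each type in both modalities, keeps
#' genes with mean expression of at least `min_mean_counts` in some type,
#' centers and scales each gene across types, and reports the Pearson
#' correlation between matching type pairs.
#'
#' @param E_c segmented cells x genes count matrix.
#' @param T_c per-cell types (levels must appear in the reference).
#' @param reference a `jsta_taxonomy` with reference cells, or a list with
#'   `E_ref`/`T_ref`.
#' @param min_mean_counts gene filter threshold (default 5).
#' @return named numeric vector of per-type Pearson correlations.
#' @export
type_correlation <- function(E_c, T_c, reference, min_mean_counts = 5) {
  E_c <- as.matrix(E_c)
  T_c <- as.character(T_c)
  mean_by_type <- function(E, Tl, types) {
    t(vapply(types, function(tt) colMeans(E[Tl == tt, , drop = FALSE]),
             numeric(ncol(E))))
  }
  types <- intersect(sort(unique(T_c)), sort(unique(reference$T_ref)))
  if (!length(types)) stopf("no shared types between segmentation and reference")
  A <- mean_by_type(E_c, T_c, types)
  B <- mean_by_type(as.matrix(reference$E_ref), reference$T_ref, types)
  keep <- apply(A, 2, max) >= min_mean_counts | apply(B, 2, max) >= min_mean_counts
  if (sum(keep) < 3) stopf("fewer than 3 genes pass the expression filter")
  A <- scale(A[, keep, drop = FALSE])
  B <- scale(B[, keep, drop = FALSE])
  A[is.nan(A)] <- 0; B[is.nan(B)] <- 0
  stats::setNames(vapply(seq_along(types),
                         function(i) cor(A[i, ], B[i, ]), numeric(1)),
                  types)
}

# n x k matrix of each point's k nearest neighbors (Euclidean, self excluded)
knn_index <- function(centroids, k) {
  n <- nrow(centroids)
  if (n <= k) stopf("need more than k = %d cells", k)
  D <- as.matrix(dist(centroids))
  diag(D) <- Inf
  t(apply(D, 1, function(row) order(row)[seq_len(k)]))
}

#' Cell-type colocalization permutation test
#'
#' The observed statistic for a type pair (a, b) is the mean, over cells of
#' type a, of the fraction of their `k_neighbors` nearest neighbors that
#' are of type b. The null is built by permuting the type labels over the
#' fixed cell positions; p-values use the add-one correction
#' `(1 + #(null >= observed)) / (1 + n_perm)` and are BH-adjusted.
#'
#' @param centroids cells x 2-or-3 coordinate matrix.
#' @param T_c per-cell type labels.
#' @param k_neighbors neighborhood size (default 20).
#' @param n_perm label permutations (default 1000).
#' @param seed integer.
#' @return list with `observed` (k' x k' neighbor-fraction matrix), `p`,
#'   `q` (BH), `n_perm`, and `types`.
#' @export
colocalization_test <- function(centroids, T_c, k_neighbors = 20,
                                n_perm = 1000, seed = 1) {
  centroids <- as.matrix(centroids)
  if (ncol(centroids) == 2) centroids <- cbind(centroids, 0)
  T_c <- as.character(T_c)
  n <- nrow(centroids)
  if (n <= k_neighbors) stopf("need more than k_neighbors cells")
  nb <- knn_index(centroids, k_neighbors)
  types <- sort(unique(T_c))
  kt <- length(types)
  y <- match(T_c, types)

  frac_matrix <- function(lab) {
    nb_lab <- matrix(lab[nb], n, k_neighbors)
    counts <- matrix(0, n, kt)
    for (t in seq_len(kt)) counts[, t] <- rowSums(nb_lab == t)
    fr <- counts / k_neighbors
    out <- matrix(NA_real_, kt, kt, dimnames = list(types, types))
    for (a in seq_len(kt)) {
      rows <- lab == a
      if (any(rows)) out[a, ] <- colMeans(fr[rows, , drop = FALSE])
    }
    out
  }

  obs <- frac_matrix(y)
  with_seed(seed, {
    ge <- matrix(0L, kt, kt)
    for (p in seq_len(n_perm)) {
      nullm <- frac_matrix(sample(y))
      ge <- ge + (!is.na(nullm) & !is.na(obs) & nullm >= obs)
    }
    pmat <- (1 + ge) / (1 + n_perm)
    pmat[is.na(obs)] <- NA_real_
    qmat <- matrix(p.adjust(pmat, method = "BH"), kt, kt,
                   dimnames = dimnames(pmat))
    list(observed = obs, p = pmat, q = qmat, n_perm = n_perm, types = types)
  })
}

#' Within-type spatial differential expression permutation test
#'
#' For every type with more than `min_cells` cells: the local expression of
#' a gene at a cell is the mean over the cell and its `k_local` nearest
#' same-type neighbors; the statistic is the variance of local expression
#' across the type's cells. The null permutes the gene's values among the
#' type's cells (destroying spatial structure, preserving the expression
#' distribution). p-values use the add-one correction and are BH-adjusted
#' jointly across all (type, gene) pairs.
#'
#' @param centroids cells x 2-or-3 coordinate matrix.
#' @param E_c cells x genes expression matrix (typically the held-out,
#'   non-marker genes).
#' @param T_c per-cell type labels.
#' @param genes_tested column names or indices to test (default: all).
#' @param min_cells only types with more than this many cells are tested
#'   (default 40).
#' @param k_local neighborhood size (default 9).
#' @param n_perm permutations (default 100).
#' @param seed integer.
#' @return list with `table` (data.frame: type, gene, statistic, p, q),
#'   `tested_types`, `skipped_types`, `n_perm`.
#' @export
spdeg_test <- function(centroids, E_c, T_c, genes_tested = NULL,
                       min_cells = 40, k_local = 9, n_perm = 100, seed = 1) {
  centroids <- as.matrix(centroids)
  if (ncol(centroids) == 2) centroids <- cbind(centroids, 0)
  E_c <- as.matrix(E_c)
  T_c <- as.character(T_c)
  if (is.null(genes_tested)) genes_tested <- seq_len(ncol(E_c))
  if (is.character(genes_tested)) genes_tested <- match(genes_tested, colnames(E_c))
  gene_names <- colnames(E_c)[genes_tested] %||% paste0("g", genes_tested)

  sizes <- table(T_c)
  tested <- names(sizes)[sizes > min_cells]
  skipped <- setdiff(names(sizes), tested)

  rows <- list()
  with_seed(seed, {
    for (tt in tested) {
      idx <- which(T_c == tt)
      X <- E_c[idx, genes_tested, drop = FALSE]
      nb <- knn_index(centroids[idx, , drop = FALSE], k_local)
      local_mean <- function(M) {
        L <- M
        for (j in seq_len(k_local)) L <- L + M[nb[, j], , drop = FALSE]
        L / (k_local + 1)
      }
      obs <- apply(local_mean(X), 2, var)
      ge <- integer(length(obs))
      for (p in seq_len(n_perm)) {
        nullv <- apply(local_mean(X[sample(nrow(X)), , drop = FALSE]), 2, var)
        ge <- ge + (nullv >= obs)
      }
      rows[[tt]] <- data.frame(type = tt, gene = gene_names,
                               statistic = obs, p = (1 + ge) / (1 + n_perm))
    }
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(tab)) tab$q <- p.adjust(tab$p, method = "BH")
  list(table = tab, tested_types = tested, skipped_types = skipped,
       n_perm = n_perm)
}
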