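#' Two-pass z-score harmonization of an expression matrix
#'
#' Aligns expression distributions across modalities (scRNA-seq reference
#' vs imaging-derived counts): first each cell (row) is centered and scaled
#' across its genes, then each gene (column) of the result is centered and
#' scaled across cells. Scaling uses the population (1/n) standard
#' deviation; zero-variance rows/columns are divided by 1 instead of 0.
#'
#' @param E numeric matrix, cells x genes.
#' @return matrix of the same shape.
#' @export
harmonize_expression <- function(E) {
  E <- as.matrix(E)
  if (nrow(E) < 2 || ncol(E) < 2) stopf("need at least 2 cells and 2 genes")
  if (!all(is.finite(E))) stopf("expression matrix contains non-finite values")
  zscore <- function(M, margin) {
    mu <- apply(M, margin, mean)
    sdev <- sqrt(apply(M, margin, function(v) mean((v - mean(v))^2)))
    sdev[sdev == 0] <- 1
    if (margin == 1) (M - mu) / sdev else sweep(sweep(M, 2, mu, "-"), 2, sdev, "/")
  }
  zscore(zscore(E, 1), 2)
}

#' Per-type mean, covariance and frequency
#'
#' @param E_ref numeric matrix, cells x genes (integer counts expected; round
#'   beforehand if the matrix was rescaled).
#' @param T_ref per-cell type labels.
#' @return list with `mu` (k x m matrix), `sigma` (list of k m-x-m sample
#'   covariance matrices), `proportions` (named, sums to 1). A type with a
#'   single cell gets a diagonal covariance filled with the pooled per-gene
#'   variance, with a warning.
#' @export
type_statistics <- function(E_ref, T_ref) {
  E_ref <- as.matrix(E_ref)
  T_ref <- as.character(T_ref)
  stopifnot(nrow(E_ref) == length(T_ref))
  types <- sort(unique(T_ref))
  m <- ncol(E_ref)
  mu <- matrix(NA_real_, length(types), m,
               dimnames = list(types, colnames(E_ref)))
  sigma <- vector("list", length(types))
  names(sigma) <- types
  pooled_var <- apply(E_ref, 2, var)
  pooled_var[is.na(pooled_var)] <- 0
  for (t in types) {
    rows <- E_ref[T_ref == t, , drop = FALSE]
    mu[t, ] <- colMeans(rows)
    if (nrow(rows) >= 2) {
      sigma[[t]] <- cov(rows)
    } else {
      warnf("type '%s' has a single cell; using diagonal pooled variance", t)
      sigma[[t]] <- diag(pooled_var, m)
    }
  }
  props <- as.numeric(table(factor(T_ref, levels = types))) / length(T_ref)
  names(props) <- types
  list(mu = mu, sigma = sigma, proportions = props)
}

#' Reference taxonomy
#'
#' Bundles a cell x gene reference matrix, per-cell type labels, per-type
#' statistics and a rooted type dendrogram used for granularity cuts. When
#' no dendrogram is supplied, one is built by average-linkage hierarchical
#' clustering of the per-type mean vectors on correlation distance, with
#' merge heights scaled by the root height so they lie in (0, 1] (a cut at
#' height 0 is then always the identity grouping).
#'
#' @param E_ref cells x genes count matrix.
#' @param T_ref per-cell type labels.
#' @param linkage optional `hclust` object over the types (labels must match
#'   the type set) or a (k-1) x 4 merge table with columns merge1, merge2,
#'   height (standard hierarchical-clustering encoding, negative = leaf).
#' @return a `jsta_taxonomy` object.
#' @export
reference_taxonomy <- function(E_ref, T_ref, linkage = NULL) {
  E_ref <- as.matrix(E_ref)
  st <- type_statistics(E_ref, T_ref)
  types <- rownames(st$mu)
  hc <- if (is.null(linkage)) type_dendrogram(st$mu) else as_type_hclust(linkage, types)
  structure(list(E_ref = E_ref, T_ref = as.character(T_ref),
                 types = types, k = length(types), m = ncol(E_ref),
                 mu = st$mu, sigma = st$sigma, proportions = st$proportions,
                 linkage = hc),
            class = "jsta_taxonomy")
}

#' @export
print.jsta_taxonomy <- function(x, ...) {
  cat(sprintf("<jsta_taxonomy> %d types, %d genes%s\n", x$k, x$m,
              if (is.null(x$E_ref)) " (parametric)" else
                sprintf(", %d reference cells", nrow(x$E_ref))))
  invisible(x)
}

# average-linkage dendrogram of type means on correlation distance,
# heights scaled so the root is at 1
type_dendrogram <- function(mu) {
  if (nrow(mu) < 2) stopf("need at least 2 types to build a dendrogram")
  cors <- suppressWarnings(cor(t(mu)))
  cors[!is.finite(cors)] <- 0
  hc <- hclust(as.dist(1 - cors), method = "average")
  hc$height <- hc$height / max(hc$height)
  hc
}

as_type_hclust <- function(linkage, types) {
  if (inherits(linkage, "hclust")) {
    hc <- linkage
  } else {
    linkage <- as.matrix(linkage)
    hc <- list(merge = cbind(as.integer(linkage[, 1]), as.integer(linkage[, 2])),
               height = as.numeric(linkage[, 3]),
               order = seq_along(types), labels = types,
               method = "supplied", call = NULL, dist.method = NULL)
    class(hc) <- "hclust"
  }
  if (is.unsorted(hc$height)) stopf("linkage is not ultrametric: heights must be non-decreasing")
  if (!setequal(hc$labels, types)) stopf("linkage labels do not match the type set")
  hc
}

#' Cut the type dendrogram at a height
#'
#' Two fine types share a group iff their merge height is at or below
#' `height`. Cuts are nested: raising the height only merges groups.
#'
#' @param taxonomy a `jsta_taxonomy` (or an `hclust` over the types).
#' @param height cut height; 0 returns the identity grouping.
#' @return named integer vector mapping each fine type to a group id, with
#'   attributes `height` and `k_groups`.
#' @export
granularity_grouping <- function(taxonomy, height) {
  hc <- if (inherits(taxonomy, "jsta_taxonomy")) taxonomy$linkage else taxonomy
  if (height < 0) stopf("height must be non-negative")
  g <- cutree(hc, h = min(height, max(hc$height)))
  if (height < min(hc$height)) g <- stats::setNames(seq_along(hc$labels), hc$labels)
  structure(as.integer(g), names = names(g) %||% hc$labels,
            height = height, k_groups = length(unique(g)))
}

#' Construct a synthetic cell-type taxonomy
#'
#' A parametric stand-in for an external scRNA-seq taxonomy: each of `k`
#' types gets a baseline mean expression with a boosted block of marker
#' genes (blocks assigned round-robin so means are well separated), a
#' positive-definite covariance (overdispersed diagonal plus a rank-one
#' component), uniform type proportions, and a dendrogram built from the
#' means.
#'
#' @param k number of types.
#' @param m number of genes.
#' @param base_mean range of baseline per-gene means (uniform draw).
#' @param marker_boost range of the additive mean boost on a type's marker
#'   block.
#' @param overdispersion variance-to-mean ratio of the diagonal covariance.
#' @param seed optional integer for reproducibility.
#' @return a `jsta_taxonomy` (parametric: no reference cells attached; use
#'   [sample_reference_cells()] to draw them).
#' @export
synthetic_taxonomy <- function(k, m, base_mean = c(15, 40),
                               marker_boost = c(40, 80),
                               overdispersion = 1.5, seed = NULL) {
  stopifnot(k >= 2, m >= k)
  with_seed(seed, {
    types <- sprintf("T%02d", seq_len(k))
    genes <- sprintf("g%03d", seq_len(m))
    lambda <- runif(m, base_mean[1], base_mean[2])
    mu <- matrix(rep(lambda, each = k), k, m, dimnames = list(types, genes))
    block <- ((seq_len(m) - 1) %% k) + 1
    for (t in seq_len(k)) {
      mu[t, block == t] <- mu[t, block == t] +
        runif(sum(block == t), marker_boost[1], marker_boost[2])
    }
    sigma <- vector("list", k)
    names(sigma) <- types
    for (t in seq_len(k)) {
      u <- rnorm(m, 0, 0.3 * sqrt(mu[t, ]))
      sigma[[t]] <- diag(overdispersion * mu[t, ], m) + tcrossprod(u)
      dimnames(sigma[[t]]) <- list(genes, genes)
    }
    structure(list(E_ref = NULL, T_ref = NULL, types = types, k = k, m = m,
                   mu = mu, sigma = sigma,
                   proportions = stats::setNames(rep(1 / k, k), types),
                   linkage = type_dendrogram(mu)),
              class = "jsta_taxonomy")
  })
}

#' Draw reference cells from a taxonomy's per-type distributions
#'
#' Samples expression profiles from each type's multivariate Gaussian (via
#' [sample_cell_expression()]), giving a cell x gene count matrix with
#' labels — a synthetic reference for training the cell-type classifier.
#'
#' @param taxonomy a `jsta_taxonomy`.
#' @param n_per_type cells per type (scalar or length-k).
#' @param seed optional integer.
#' @return the taxonomy with `E_ref` and `T_ref` filled in (statistics are
#'   kept parametric, not re-estimated).
#' @export
sample_reference_cells <- function(taxonomy, n_per_type = 50, seed = NULL) {
  k <- taxonomy$k
  n_per_type <- rep_len(n_per_type, k)
  with_seed(seed, {
    rows <- list()
    labs <- character(0)
    for (t in seq_len(k)) {
      tt <- taxonomy$types[t]
      draws <- t(vapply(seq_len(n_per_type[t]),
                        function(i) sample_cell_expression(taxonomy, tt),
                        numeric(taxonomy$m)))
      rows[[t]] <- draws
      labs <- c(labs, rep(tt, n_per_type[t]))
    }
    taxonomy$E_ref <- do.call(rbind, rows)
    colnames(taxonomy$E_ref) <- colnames(taxonomy$mu)
    taxonomy$T_ref <- labs
    taxonomy
  })
}
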