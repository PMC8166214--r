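#' @keywords internal
"_PACKAGE"

#' @useDynLib jsta, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cov cutree dist hclust as.dist cor var rnorm runif
#'   sd p.adjust predict as.dendrogram quantile
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. seed = NULL leaves the current stream in place.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# voxel index (1-based triple) of physical coordinates on a grid
coord_to_voxel <- function(xyz, origin, pixel_size) {
  sweep(xyz, 2, origin, "-") %/% pixel_size + 1L
}

# physical center of 1-based voxel indices
voxel_center <- function(ijk, origin, pixel_size) {
  sweep((ijk - 0.5) * pixel_size, 2, origin, "+")
}

# linear index into a 3D array from 1-based (i,j,k) columns
linear_index <- function(ijk, dims) {
  as.integer(ijk[, 1] + dims[1] * (ijk[, 2] - 1) +
               dims[1] * dims[2] * (ijk[, 3] - 1))
}

# inverse of linear_index: n x 3 matrix of 1-based voxel indices
array_index <- function(lin, dims) {
  lin0 <- lin - 1L
  i <- lin0 %% dims[1]
  j <- (lin0 %/% dims[1]) %% dims[2]
  k <- lin0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}
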