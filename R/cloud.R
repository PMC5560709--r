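#' Weighted 3D point cloud
#'
#' The common representation fitted by the coarse-graining model: `N`
#' points in Angstrom with strictly positive weights. Atomic structures
#' carry unit weights; point clouds derived from density maps carry
#' density-derived weights rescaled to mean one, so the effective number
#' of observations equals the number of surviving voxels.
#'
#' @param positions numeric N x 3 matrix of coordinates (Angstrom).
#' @param weights numeric vector of N positive weights; defaults to 1.
#' @param source_id free-text provenance tag (PDB/EMDB code or "synthetic").
#' @return An object of class `point_cloud` with elements `positions`,
#'   `weights` and `source_id`.
#' @examples
#' cl <- point_cloud(matrix(rnorm(30), ncol = 3))
#' n_points(cl)
#' @export
point_cloud <- function(positions, weights = NULL, source_id = "synthetic") {
  positions <- as.matrix(positions)
  if (is.null(dim(positions)) || ncol(positions) != 3)
    stop("positions must be an N x 3 matrix")
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (n < 1) stop("empty point cloud: need at least one point")
  if (!all(is.finite(positions))) stop("non-finite coordinates in point cloud")
  if (is.null(weights)) weights <- rep(1.0, n)
  weights <- as.numeric(weights)
  if (length(weights) != n) stop("weights must have one entry per point")
  if (!all(is.finite(weights)) || any(weights <= 0))
    stop("weights must be finite and > 0")
  structure(
    list(positions = positions, weights = weights,
         source_id = as.character(source_id)[1]),
    class = "point_cloud"
  )
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points, total weight %.6g, source '%s'\n",
              nrow(x$positions), sum(x$weights), x$source_id))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$positions)

#' Total weight of a cloud
#'
#' For atomic input this equals the atom count; for map-derived clouds it
#' equals the surviving voxel count (weights are mean-1 normalized).
#' @param cloud a `point_cloud`.
#' @return numeric total weight.
#' @export
total_weight <- function(cloud) sum(cloud$weights)

.as_cloud <- function(x) {
  if (inherits(x, "point_cloud")) return(x)
  point_cloud(x)
}
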