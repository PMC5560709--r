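## Incremental 3D convex hull, used only to obtain the reference volume
## for the radial distribution function of a finite, non-periodic bead
## system. No qhull binding is available in the installed stack; for the
## point counts involved (hundreds to a few thousand sites) the O(n * f)
## incremental construction below is ample.

#' Volume of the convex hull of a 3D point set
#'
#' @param points M x 3 matrix.
#' @return hull volume in cubic Angstrom; 0 for degenerate (coplanar or
#'   smaller) inputs.
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' convex_hull_volume(cube)  # 1
#' @export
convex_hull_volume <- function(points) {
  P <- as.matrix(points)
  if (ncol(P) != 3) stop("points must be M x 3")
  P <- unique(P)
  n <- nrow(P)
  if (n < 4) return(0)
  scale <- max(apply(P, 2, function(v) diff(range(v))))
  if (scale == 0) return(0)
  eps <- 1e-10 * scale

  ## --- initial non-degenerate tetrahedron -------------------------------
  i1 <- which.min(P[, 1])
  d1 <- rowSums(sweep(P, 2, P[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] <= eps^2) return(0)
  e1 <- P[i2, ] - P[i1, ]
  ## farthest from line i1-i2
  w <- sweep(P, 2, P[i1, ])
  t <- (w %*% e1) / sum(e1^2)
  dl <- rowSums((w - t %*% t(e1))^2)
  i3 <- which.max(dl)
  if (dl[i3] <= eps^2) return(0)
  nrm <- .cross3(e1, P[i3, ] - P[i1, ])
  dp <- abs(w %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(dp)
  if (dp[i4] <= eps) return(0)

  verts <- c(i1, i2, i3, i4)
  centroid <- colMeans(P[verts, ])
  ## faces as vertex index triples, oriented outward (away from centroid)
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- lapply(faces, function(f) .orient_face(P, f, centroid))

  remaining <- setdiff(seq_len(n), verts)
  for (p in remaining) {
    x <- P[p, ]
    vis <- vapply(faces, function(f) .face_dist(P, f, x) > eps, logical(1))
    if (!any(vis)) next
    ## horizon = edges of visible faces shared with an invisible face
    edges <- do.call(rbind, lapply(faces[vis], function(f)
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    faces <- faces[!vis]
    newf <- lapply(seq_len(nrow(horizon)), function(e)
      .orient_face(P, c(horizon[e, ], p), centroid))
    faces <- c(faces, newf)
  }

  ## volume: signed tetrahedra from the centroid to each outward face
  v <- 0
  for (f in faces) {
    a <- P[f[1], ] - centroid; b <- P[f[2], ] - centroid
    cc <- P[f[3], ] - centroid
    v <- v + det(rbind(a, b, cc)) / 6
  }
  abs(v)
}

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

## signed distance of x above face plane (positive = outside)
.face_dist <- function(P, f, x) {
  nrm <- .cross3(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
  sum(nrm * (x - P[f[1], ])) / sqrt(sum(nrm^2))
}

.orient_face <- function(P, f, centroid) {
  if (.face_dist(P, f, centroid) > 0) f[c(1, 3, 2)] else f
}
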