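#' Radius of gyration
#'
#' Root weighted mean squared distance to the weighted centroid.
#' @param points N x 3 matrix or [point_cloud()].
#' @param weights optional weights (taken from the cloud if omitted).
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(points, weights = NULL) {
  if (inherits(points, "point_cloud")) {
    if (is.null(weights)) weights <- points$weights
    points <- points$positions
  }
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(weights)) weights <- rep(1, n)
  ctr <- colSums(points * weights) / sum(weights)
  sqrt(sum(weights * rowSums(sweep(points, 2, ctr)^2)) / sum(weights))
}

#' Radial distribution function of bead configurations
#'
#' Histogram of all within-frame pair distances pooled over frames, each
#' bin normalized by the ideal-gas expectation
#' `n_pairs * (shell volume) / V_ref`. For a finite, non-periodic system
#' there is no box volume; the reference volume defaults to the convex
#' hull of the pooled configurations, which makes `g` plateau near 1 in
#' the bulk of a uniform system.
#'
#' @param frames a K x 3 matrix or a list of such matrices (frames of a
#'   trajectory/trace).
#' @param bin_width bin width in Angstrom (default 0.25).
#' @param r_max histogram range; defaults to the largest pair distance.
#'   Bins beyond the system extent are ~0 by construction.
#' @param v_ref reference volume override (Angstrom^3); default convex
#'   hull volume of the pooled points.
#' @return list of class `rdf_result` with `bin_centers`, `g`,
#'   `bin_width`, `n_frames`, `v_ref`, `counts`.
#' @export
rdf <- function(frames, bin_width = 0.25, r_max = NULL, v_ref = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, .as_beads)
  if (any(vapply(frames, nrow, 1L) < 2L)) stop("need K >= 2 beads per frame")
  dists <- unlist(lapply(frames, function(X) as.numeric(stats::dist(X))))
  if (is.null(r_max)) r_max <- max(dists) + bin_width
  breaks <- seq(0, r_max + bin_width, by = bin_width)
  h <- graphics::hist(dists[dists < max(breaks)], breaks = breaks,
                      plot = FALSE)
  pooled <- do.call(rbind, frames)
  if (is.null(v_ref)) v_ref <- convex_hull_volume(pooled)
  if (!is.finite(v_ref) || v_ref <= 0)
    stop("degenerate reference volume; supply v_ref explicitly")
  n_pairs_total <- sum(vapply(frames, function(X) nrow(X) * (nrow(X) - 1) / 2,
                              numeric(1)))
  shell <- 4 / 3 * pi * diff(breaks^3)
  expected <- n_pairs_total * shell / v_ref
  structure(list(bin_centers = h$mids, g = h$counts / expected,
                 bin_width = bin_width, n_frames = length(frames),
                 v_ref = v_ref, counts = h$counts),
            class = "rdf_result")
}

#' Boltzmann inversion of a radial distribution function
#'
#' `w(r) = -log g(r)` in model units (`k_B T = 1`); empty bins (`g = 0`)
#' map to `Inf`.
#' @param rdf_result an `rdf_result` from [rdf()].
#' @return list with `bin_centers` and `pmf`.
#' @export
pmf_from_rdf <- function(rdf_result) {
  g <- rdf_result$g
  pmf <- ifelse(g > 0, -log(g), Inf)
  list(bin_centers = rdf_result$bin_centers, pmf = pmf)
}

#' Power-law fit by log-log least squares
#'
#' Ordinary least squares of `log y` on `log x`, reported as
#' `y = prefactor * x^exponent`.
#' @param x,y positive numeric vectors (>= 2 points).
#' @return list with `prefactor`, `exponent`, `residuals` (log scale).
#' @export
fit_power_law <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2)
    stop("need >= 2 paired points")
  if (any(x <= 0) || any(y <= 0)) stop("power-law fit needs positive values")
  fit <- stats::lm.fit(cbind(1, log(x)), log(y))
  list(prefactor = exp(fit$coefficients[[1]]),
       exponent = fit$coefficients[[2]],
       residuals = as.numeric(fit$residuals))
}

## nearest-neighbor open path from a start vertex on distance matrix D
.nn_path <- function(D, start) {
  K <- nrow(D)
  path <- integer(K); used <- logical(K)
  path[1] <- start; used[start] <- TRUE
  for (i in 2:K) {
    d <- D[path[i - 1], ]; d[used] <- Inf
    path[i] <- which.min(d)
    used[path[i]] <- TRUE
  }
  path
}

.path_length <- function(D, path)
  sum(D[cbind(path[-length(path)], path[-1])])

## exact open-path TSP by Held-Karp dynamic programming (K <= 12)
.tsp_exact <- function(D) {
  K <- nrow(D)
  nsub <- 2^K
  best <- matrix(Inf, nsub, K)       # best[S, j]: path over set S ending at j
  parent <- matrix(NA_integer_, nsub, K)
  for (j in seq_len(K)) best[2^(j - 1) + 1, j] <- 0
  for (S in seq_len(nsub - 1)) {
    members <- which(bitwAnd(S, 2^(seq_len(K) - 1)) > 0)
    if (length(members) < 2) next
    for (j in members) {
      Sprev <- S - 2^(j - 1)
      prev <- members[members != j]
      cand <- best[Sprev + 1, prev] + D[prev, j]
      b <- which.min(cand)
      best[S + 1, j] <- cand[b]
      parent[S + 1, j] <- prev[b]
    }
  }
  full <- nsub - 1
  end <- which.min(best[full + 1, ])
  path <- integer(K); path[K] <- end
  S <- full
  for (i in K:2) {
    p <- parent[S + 1, path[i]]
    S <- S - 2^(path[i] - 1)
    path[i - 1] <- p
  }
  path
}

#' Reorder beads along a short path
#'
#' The mixture model is invariant under bead permutations, so beads can be
#' renumbered so that spatially close beads have similar indices by
#' finding a short open path that visits every bead exactly once. For
#' `K <= 12` the optimum is computed exactly by Held-Karp dynamic
#' programming; larger instances use a heuristic (nearest-neighbor
#' construction from the bead farthest from the centroid, refined by
#' 2-opt until no improving reversal remains), whose result never exceeds
#' the nearest-neighbor path length.
#'
#' @param X K x 3 bead positions (K >= 2).
#' @return integer permutation of `1..K` (visit order).
#' @export
reorder_beads <- function(X) {
  X <- .as_beads(X)
  K <- nrow(X)
  if (K < 2) stop("need K >= 2 beads to order")
  D <- as.matrix(stats::dist(X))
  if (K <= 12) return(.tsp_exact(D))
  ## extreme point: farthest from the centroid
  ctr <- colMeans(X)
  start <- which.max(rowSums(sweep(X, 2, ctr)^2))
  path <- .nn_path(D, start)
  ## 2-opt: reverse segments while an improvement exists
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (a in 1:(K - 1)) {
      for (b in (a + 1):K) {
        ## cost change of reversing path[a..b] in an open path
        before <- (if (a > 1) D[path[a - 1], path[a]] else 0) +
                  (if (b < K) D[path[b], path[b + 1]] else 0)
        after <- (if (a > 1) D[path[a - 1], path[b]] else 0) +
                 (if (b < K) D[path[a], path[b + 1]] else 0)
        if (after < before - 1e-12) {
          path[a:b] <- path[b:a]
          improved <- TRUE
        }
      }
    }
  }
  path
}

#' Render a bead model onto a map grid
#'
#' Sum of equal-amplitude isotropic Gaussian kernels, one per bead,
#' sampled on the template's grid. Each kernel is a normalized density
#' multiplied by the voxel volume, so the grid total approximates the bead
#' count (up to grid truncation).
#'
#' @param model `bead_model` or K x 3 matrix.
#' @param template a [density_map()] providing grid geometry.
#' @param kernel_width Gaussian standard deviation in Angstrom (a bead
#'   model's `s_mean` is the natural default).
#' @return a [density_map()] on the template geometry.
#' @export
render_model_to_map <- function(model, template, kernel_width) {
  X <- if (is.matrix(model)) model else model$positions
  X <- .as_beads(X)
  stopifnot(inherits(template, "density_map"))
  d <- dim(template$grid)
  ax <- lapply(1:3, function(a)
    template$origin[a] + (seq_len(d[a]) - 1) * template$voxel_size[a])
  lo <- vapply(ax, min, 1); hi <- vapply(ax, max, 1)
  if (any(apply(X, 2, min) < lo - 3 * kernel_width) ||
      any(apply(X, 2, max) > hi + 3 * kernel_width))
    warning("beads lie outside the template bounding box")
  vol <- prod(template$voxel_size)
  grid <- array(0, d)
  norm <- vol / (2 * pi * kernel_width^2)^1.5
  for (k in seq_len(nrow(X))) {
    gx <- exp(-(ax[[1]] - X[k, 1])^2 / (2 * kernel_width^2))
    gy <- exp(-(ax[[2]] - X[k, 2])^2 / (2 * kernel_width^2))
    gz <- exp(-(ax[[3]] - X[k, 3])^2 / (2 * kernel_width^2))
    grid <- grid + norm * (gx %o% gy %o% gz)
  }
  density_map(grid, template$voxel_size, template$origin,
              template$resolution_annotation)
}

#' Cross-correlation between two maps on the same grid
#'
#' Pearson correlation over voxels; with thresholds, over voxels where
#' either map exceeds its threshold.
#' @param map_a,map_b [density_map()] objects with identical geometry.
#' @param threshold_a,threshold_b optional density thresholds.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
cross_correlation <- function(map_a, map_b, threshold_a = -Inf,
                              threshold_b = -Inf) {
  if (!identical(dim(map_a$grid), dim(map_b$grid)))
    stop("maps must share grid geometry")
  sel <- map_a$grid > threshold_a | map_b$grid > threshold_b
  a <- map_a$grid[sel]; b <- map_b$grid[sel]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero-variance map")
  stats::cor(a, b)
}

#' Maximum cross-correlation over rendering kernel widths
#'
#' Renders the model at each candidate width and reports the best
#' correlation with the template (the model is assumed already in the map
#' frame; no translational/rotational search).
#' @inheritParams render_model_to_map
#' @param widths candidate kernel widths (Angstrom).
#' @return list with `cc`, `kernel_width` and the per-width `table`.
#' @export
max_cross_correlation <- function(model, template, widths) {
  ccs <- vapply(widths, function(w)
    cross_correlation(render_model_to_map(model, template, w), template),
    numeric(1))
  best <- which.max(ccs)
  list(cc = ccs[best], kernel_width = widths[best],
       table = data.frame(kernel_width = widths, cc = ccs))
}

#' Anisotropic network model normal modes
#'
#' Builds the standard ANM Hessian (uniform spring constant 1): sites
#' closer than `cutoff` are connected; each contact contributes the 3 x 3
#' super-element `-(r_hat r_hat^T)` off-diagonal, and diagonal blocks are
#' the negated row sums. Eigenvectors of the symmetric Hessian are the
#' modes; eigenvalues below `1e-8 * max` count as the (six) rigid-body
#' zero modes.
#'
#' @param sites M x 3 site positions (C-alpha atoms or beads).
#' @param cutoff contact cutoff in Angstrom (15 for C-alpha networks;
#'   `7 * R_CG` is the adopted choice for bead networks).
#' @return list of class `mode_set`: `eigenvalues` (ascending), `modes`
#'   (3M x 3M, columns are orthonormal modes), `n_zero_modes`, `cutoff`.
#' @export
anm_modes <- function(sites, cutoff) {
  X <- .as_beads(sites)
  M <- nrow(X)
  D <- as.matrix(stats::dist(X))
  adj <- D > 0 & D <= cutoff
  ## connectivity check (BFS)
  seen <- logical(M); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen))
    stop("network disconnected at cutoff ", cutoff,
         ": component containing site 1 has ", sum(seen), " of ", M,
         " sites")
  H <- matrix(0, 3 * M, 3 * M)
  for (i in 1:(M - 1)) for (j in (i + 1):M) {
    if (!adj[i, j]) next
    r <- X[j, ] - X[i, ]
    rr <- tcrossprod(r) / sum(r^2)
    bi <- 3 * (i - 1) + 1:3; bj <- 3 * (j - 1) + 1:3
    H[bi, bj] <- H[bi, bj] - rr
    H[bj, bi] <- H[bj, bi] - rr
    H[bi, bi] <- H[bi, bi] + rr
    H[bj, bj] <- H[bj, bj] + rr
  }
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  ev <- eig$values[ord]
  modes <- eig$vectors[, ord, drop = FALSE]
  nz <- sum(ev < 1e-8 * max(ev))
  structure(list(eigenvalues = ev, modes = modes, n_zero_modes = nz,
                 cutoff = cutoff), class = "mode_set")
}

#' Overlap between a mode and a displacement vector
#'
#' Normalized absolute inner product `|m . d| / (||m|| ||d||)`; 1 when the
#' displacement lies along the mode, 0 when orthogonal.
#' @param mode,delta numeric vectors of equal length, both nonzero.
#' @return value in `[0, 1]`.
#' @export
mode_overlap <- function(mode, delta) {
  mode <- as.numeric(mode); delta <- as.numeric(delta)
  if (length(mode) != length(delta)) stop("dimension mismatch")
  nm <- sqrt(sum(mode^2)); nd <- sqrt(sum(delta^2))
  if (nm == 0 || nd == 0) stop("zero vector has no direction")
  abs(sum(mode * delta)) / (nm * nd)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Rotates and translates `mobile` onto `target` minimizing the RMSD;
#' used to compute displacement vectors between conformational states
#' before mode-overlap analysis.
#' @param mobile,target matched M x 3 coordinate sets.
#' @return list with transformed `coords`, `rotation`, `rmsd`.
#' @export
superpose <- function(mobile, target) {
  A <- .as_beads(mobile); B <- .as_beads(target)
  if (nrow(A) != nrow(B)) stop("site counts differ")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(A0, B0))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  coords <- sweep(A0 %*% t(R), 2, cb, "+")
  list(coords = coords, rotation = R,
       rmsd = sqrt(mean(rowSums((coords - B)^2))))
}

#' Thin-plate-spline interpolation of a vector field
#'
#' Fits a 3D thin-plate spline (radial kernel `||r||` plus an affine
#' part) per vector component through the control values exactly (no
#' smoothing) and evaluates it at the query points. Used to carry normal
#' modes computed on beads over to atomic positions.
#'
#' @param control_points M x 3 control sites (>= 4, non-coplanar).
#' @param values M x d values at the control sites.
#' @param query_points Q x 3 evaluation sites.
#' @return Q x d interpolated values.
#' @export
tps_interpolate <- function(control_points, values, query_points) {
  P <- .as_beads(control_points)
  V <- as.matrix(values)
  Q <- .as_beads(query_points)
  M <- nrow(P)
  if (M < 4) stop("need at least 4 control points")
  if (nrow(V) != M) stop("one value row per control point required")
  Kmat <- as.matrix(stats::dist(P))          # 3D TPS kernel: |r|
  Pm <- cbind(1, P)
  sys <- rbind(cbind(Kmat, Pm), cbind(t(Pm), matrix(0, 4, 4)))
  rhs <- rbind(V, matrix(0, 4, ncol(V)))
  rc <- rcond(sys)
  if (!is.finite(rc) || rc < 1e-14)
    stop("degenerate control geometry (coplanar or coincident points)")
  coef <- solve(sys, rhs)
  coef <- coef + solve(sys, rhs - sys %*% coef)   # one refinement step
  W <- coef[1:M, , drop = FALSE]
  Aff <- coef[(M + 1):(M + 4), , drop = FALSE]
  ## distances computed per control point: the cross-product shortcut
  ## loses ~1e-8 to cancellation, visible at the interpolation nodes
  D <- vapply(seq_len(M),
              function(m) sqrt(rowSums(sweep(Q, 2, P[m, ])^2)),
              numeric(nrow(Q)))
  D %*% W + cbind(1, Q) %*% Aff
}
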