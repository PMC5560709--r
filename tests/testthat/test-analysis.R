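test_that("radius of gyration: closed forms and spherical limit", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1, 3)), 0)
  ## weighted: mass at 0 (w=3) and 4 (w=1): centroid 1, Rg = sqrt(3)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(4, 0, 0)),
                                  weights = c(3, 1)), sqrt(3))
  ## uniform points on a sphere surface of radius R -> Rg -> R
  set.seed(101)
  v <- matrix(rnorm(3 * 4000), ncol = 3)
  v <- 7 * v / sqrt(rowSums(v^2))
  expect_equal(radius_of_gyration(v), 7, tolerance = 0.02)
})

test_that("convex hull volume: cube, tetrahedron, sphere, degeneracy", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 3
  expect_equal(convex_hull_volume(cube), 27)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(convex_hull_volume(tet), 1 / 6)
  ## interior points must not change the hull
  set.seed(102)
  inner <- matrix(runif(300, 0.2, 2.8), ncol = 3)
  expect_equal(convex_hull_volume(rbind(cube, inner)), 27)
  ## dense sampling of a ball approaches its volume from below
  b <- matrix(rnorm(3 * 3000), ncol = 3)
  b <- b * runif(3000)^(1 / 3) / sqrt(rowSums(b^2))
  vol <- convex_hull_volume(b)
  expect_lt(vol, 4 / 3 * pi)
  expect_gt(vol, 0.9 * 4 / 3 * pi)
  ## coplanar input: volume zero
  expect_equal(convex_hull_volume(cbind(matrix(runif(20), 10, 2), 0)), 0)
})

test_that("rdf: isolated pair, rigid-motion invariance, ideal gas plateau", {
  ## two beads at distance d: single nonzero bin at d
  X <- rbind(c(0, 0, 0), c(3.1, 0, 0))
  r <- rdf(X, bin_width = 0.5, r_max = 5, v_ref = 100)
  nz <- which(r$counts > 0)
  expect_length(nz, 1)
  expect_lt(abs(r$bin_centers[nz] - 3.1), 0.5)
  ## rigid motion leaves g unchanged
  set.seed(111)
  frames <- lapply(1:3, function(i) matrix(runif(60, 0, 8), 20, 3))
  r1 <- rdf(frames, bin_width = 0.5)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  frames_r <- lapply(frames, function(F) sweep(F %*% t(R), 2, c(5, -2, 1), "+"))
  r2 <- rdf(frames_r, bin_width = 0.5)
  expect_equal(r1$g, r2$g, tolerance = 1e-6)
  ## ideal gas in a cube: bulk bins within Poisson + boundary budget
  set.seed(112)
  L <- 30
  frames <- lapply(1:4, function(i) matrix(runif(3 * 1500, 0, L), ncol = 3))
  ri <- rdf(frames, bin_width = 0.25, r_max = 2, v_ref = L^3)
  sel <- ri$bin_centers >= 0.75 & ri$bin_centers <= 2
  for (b in which(sel)) {
    expected <- ri$counts[b] / ri$g[b]
    budget <- 3 / sqrt(expected) + 1.5 * ri$bin_centers[b] / L
    expect_lt(abs(ri$g[b] - 1), budget)
  }
})

test_that("pmf is the negative log of g with infinities at empty bins", {
  r <- structure(list(bin_centers = 1:4, g = c(1, exp(1), 0, 0.5),
                      bin_width = 1, n_frames = 1), class = "rdf_result")
  p <- pmf_from_rdf(r)
  expect_equal(p$pmf[1], 0)
  expect_equal(p$pmf[2], -1)
  expect_equal(p$pmf[3], Inf)
  expect_equal(p$pmf[4], log(2))
})

test_that("power-law fit: exact data, two points, OLS oracle", {
  x <- c(1, 2, 5, 10, 20)
  y <- 2 * x^-0.4
  f <- fit_power_law(x, y)
  expect_equal(f$prefactor, 2, tolerance = 1e-10)
  expect_equal(f$exponent, -0.4, tolerance = 1e-10)
  expect_lt(max(abs(f$residuals)), 1e-10)
  f2 <- fit_power_law(c(2, 8), c(3, 12))
  expect_equal(f2$prefactor * c(2, 8)^f2$exponent, c(3, 12),
               tolerance = 1e-10)
  ## noisy data against the normal-equation closed form
  set.seed(121)
  y2 <- 3 * x^0.7 * exp(rnorm(5, sd = 0.1))
  f3 <- fit_power_law(x, y2)
  Xd <- cbind(1, log(x))
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% log(y2))
  expect_equal(log(f3$prefactor), beta[1], tolerance = 1e-10)
  expect_equal(f3$exponent, beta[2], tolerance = 1e-10)
  expect_error(fit_power_law(c(1, -1), c(1, 1)), "positive")
})

test_that("bead reordering: line recovery, brute-force optimality, 2-opt bound", {
  ## points scrambled on a line: sorted order (or reversal), length 5
  X <- cbind(c(0, 5, 1, 4, 2, 3), 0, 0)
  ord <- reorder_beads(X)
  xs <- X[ord, 1]
  expect_true(all(diff(xs) == 1) || all(diff(xs) == -1))
  expect_equal(path_len(X, ord), 5)
  ## K = 2
  X2 <- matrix(rnorm(6), 2, 3)
  expect_equal(path_len(X2, reorder_beads(X2)), dist(X2)[1])
  ## random K = 8: equals brute force, never worse than nearest-neighbor
  set.seed(131)
  for (rep in 1:4) {
    X8 <- matrix(runif(24, 0, 5), 8, 3)
    ord8 <- reorder_beads(X8)
    bf <- brute_tsp(X8)
    expect_equal(path_len(X8, ord8), bf$length, tolerance = 1e-9)
  }
})

test_that("map rendering: peaks, mass and cross-correlation behavior", {
  template <- density_map(array(0, c(15, 15, 15)), voxel_size = 1,
                          origin = c(-7, -7, -7))
  ## single bead at a voxel center: maximum there
  m1 <- render_model_to_map(matrix(c(0, 0, 0), 1, 3), template, 1.2)
  expect_equal(which.max(m1$grid),
               which(m1$grid == m1$grid[8, 8, 8]))
  ## two distant beads: two equal local maxima
  m2 <- render_model_to_map(rbind(c(-4, 0, 0), c(4, 0, 0)), template, 1)
  expect_equal(m2$grid[4, 8, 8], m2$grid[12, 8, 8], tolerance = 1e-9)
  ## integrated density ~ bead count (kernel mass 1 per bead)
  expect_equal(sum(m2$grid), 2, tolerance = 0.01)
  ## correlation identities
  expect_equal(cross_correlation(m2, m2), 1)
  neg <- density_map(-m2$grid, m2$voxel_size, m2$origin)
  expect_equal(cross_correlation(m2, neg), -1)
  ## shuffled copy decorrelates
  set.seed(141)
  shuf <- density_map(array(sample(m2$grid), dim(m2$grid)),
                      m2$voxel_size, m2$origin)
  n_vox <- length(m2$grid)
  expect_lt(abs(cross_correlation(m2, shuf)), 3 / sqrt(n_vox) + 0.02)
  expect_error(cross_correlation(m2, density_map(array(1, dim(m2$grid)),
                                                 1, c(0, 0, 0))),
               "zero-variance")
  ## maximum-CC scan prefers the rendering width used to make the target
  target <- render_model_to_map(rbind(c(-4, 0, 0), c(4, 0, 0)), template, 2)
  mx <- max_cross_correlation(rbind(c(-4, 0, 0), c(4, 0, 0)), target,
                              widths = c(0.5, 1, 2, 4))
  expect_equal(mx$kernel_width, 2)
  expect_gt(mx$cc, 0.999)
})

test_that("ANM: diatomic counts, six zero modes, Hessian vs finite differences", {
  ## two connected sites: exactly one nonzero (stretch) mode
  two <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  ms <- anm_modes(two, cutoff = 2)
  expect_equal(ms$n_zero_modes, 5)
  expect_equal(sum(ms$eigenvalues > 1e-8), 1)
  ## a connected random network has exactly 6 rigid-body modes
  set.seed(151)
  X <- matrix(rnorm(30) * 2, 10, 3)
  msx <- anm_modes(X, cutoff = 15)
  expect_equal(msx$n_zero_modes, 6)
  expect_equal(crossprod(msx$modes), diag(30), tolerance = 1e-8)
  ## Hessian equals numerical second derivatives of the harmonic energy
  cutoff <- 6
  energy <- function(v) {
    Y <- matrix(v, 10, 3, byrow = TRUE)
    D0 <- as.matrix(dist(X)); D <- as.matrix(dist(Y))
    adj <- D0 > 0 & D0 <= cutoff
    sum(0.5 * (D[adj] - D0[adj])^2) / 2   # each contact counted twice
  }
  ms6 <- anm_modes(X, cutoff = cutoff)
  v0 <- as.numeric(t(X))
  h <- 1e-4
  Hn <- matrix(0, 30, 30)
  for (i in 1:30) for (j in i:30) {
    vpp <- v0; vpp[i] <- vpp[i] + h; vpp[j] <- vpp[j] + h
    vpm <- v0; vpm[i] <- vpm[i] + h; vpm[j] <- vpm[j] - h
    vmp <- v0; vmp[i] <- vmp[i] - h; vmp[j] <- vmp[j] + h
    vmm <- v0; vmm[i] <- vmm[i] - h; vmm[j] <- vmm[j] - h
    Hn[i, j] <- Hn[j, i] <-
      (energy(vpp) - energy(vpm) - energy(vmp) + energy(vmm)) / (4 * h^2)
  }
  Hanm <- ms6$modes %*% diag(ms6$eigenvalues) %*% t(ms6$modes)
  expect_equal(Hanm, Hn, tolerance = 1e-3)
  ## disconnected network errors
  far <- rbind(X, X + 100)
  expect_error(anm_modes(far, cutoff = 6), "disconnected")
})

test_that("mode overlap: parallel, orthogonal, Parseval over a basis", {
  set.seed(161)
  m <- rnorm(12)
  expect_equal(mode_overlap(m, 3 * m), 1)
  expect_equal(mode_overlap(c(1, 0, 0, 0), c(0, 1, 0, 0)), 0)
  expect_error(mode_overlap(m, numeric(12)), "zero vector")
  ## complete orthonormal basis: sum of squared overlaps = 1
  ms <- anm_modes(matrix(rnorm(18) * 2, 6, 3), cutoff = 20)
  d <- rnorm(18)
  ov <- vapply(seq_len(18), function(k) mode_overlap(ms$modes[, k], d),
               numeric(1))
  expect_equal(sum(ov^2), 1, tolerance = 1e-9)
})

test_that("superposition: exact rigid recovery and overlap invariance", {
  set.seed(171)
  A <- matrix(rnorm(36) * 3, 12, 3)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  B <- sweep(A %*% t(R), 2, c(4, -7, 2), "+")
  sp <- superpose(B, A)
  expect_lt(sp$rmsd, 1e-10)
  expect_equal(sp$coords, A, tolerance = 1e-9)
  ## displacement-based overlap is invariant under rigid motion of the
  ## second conformer when it is superposed first
  open <- A
  closed <- A + matrix(rnorm(36, sd = 0.5), 12, 3)
  ms <- anm_modes(open, cutoff = 20)
  ov_ref <- {
    d <- as.numeric(t(superpose(closed, open)$coords - open))
    vapply(7:9, function(k) mode_overlap(ms$modes[, k], d), numeric(1))
  }
  closed_moved <- sweep(closed %*% t(R), 2, c(-3, 5, 9), "+")
  ov_moved <- {
    d <- as.numeric(t(superpose(closed_moved, open)$coords - open))
    vapply(7:9, function(k) mode_overlap(ms$modes[, k], d), numeric(1))
  }
  expect_equal(ov_moved, ov_ref, tolerance = 1e-6)
})

test_that("thin-plate spline: interpolation, affine reproduction, RBF oracle", {
  set.seed(181)
  ctrl <- matrix(rnorm(45) * 2, 15, 3)
  vals <- cbind(sin(ctrl[, 1]), ctrl[, 2] * ctrl[, 3], cos(ctrl[, 3]))
  ## control points reproduced exactly
  out <- tps_interpolate(ctrl, vals, ctrl)
  expect_lt(max(abs(out - vals)), 1e-8)
  ## affine fields reproduced everywhere
  Aff <- matrix(rnorm(12), 4, 3)
  affv <- cbind(1, ctrl) %*% Aff
  q <- matrix(rnorm(30) * 3, 10, 3)
  out_aff <- tps_interpolate(ctrl, affv, q)
  expect_equal(out_aff, cbind(1, q) %*% Aff, tolerance = 1e-6)
  ## independent normal-equation RBF solve on scalar field
  f <- vals[, 1, drop = FALSE]
  Km <- as.matrix(dist(ctrl))
  P <- cbind(1, ctrl)
  sys <- rbind(cbind(Km, P), cbind(t(P), matrix(0, 4, 4)))
  coef <- solve(sys, rbind(f, matrix(0, 4, 1)))
  Dq <- sqrt(outer(rowSums(q^2), rowSums(ctrl^2), "+") -
               2 * q %*% t(ctrl))
  oracle <- Dq %*% coef[1:15, ] + cbind(1, q) %*% coef[16:19, ]
  expect_equal(tps_interpolate(ctrl, f, q), oracle, tolerance = 1e-8)
  ## degenerate geometry errors
  flat <- cbind(matrix(rnorm(20), 10, 2), 0)
  expect_error(tps_interpolate(flat, matrix(1, 10, 1), q), "degenerate")
})
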