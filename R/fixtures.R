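#' Synthetic cloud of well-separated Gaussian blobs
#'
#' Samples the mixture model's own generative process: blob centers on a
#' jittered cubic grid with the requested spacing, points drawn from
#' spherical Gaussians around them. Ground truth is returned for
#' parameter-recovery tests. The default spacing/sd ratio of 10 keeps the
#' blobs well separated (ratio >= 5 is the intended regime).
#'
#' @param n_blobs number of blobs.
#' @param center_spacing grid spacing of the blob centers (Angstrom).
#' @param blob_sd standard deviation of each blob (Angstrom).
#' @param points_per_blob points drawn per blob.
#' @param seed optional integer seed.
#' @return list with `cloud` (a [point_cloud()]), `centers`
#'   (n_blobs x 3) and `sd`.
#' @export
make_blob_cloud <- function(n_blobs = 5, center_spacing = 10, blob_sd = 1,
                            points_per_blob = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  side <- ceiling(n_blobs^(1 / 3))
  grid <- as.matrix(expand.grid(0:(side - 1), 0:(side - 1), 0:(side - 1)))
  grid <- grid[seq_len(n_blobs), , drop = FALSE] * center_spacing
  centers <- grid + matrix(stats::runif(3 * n_blobs, -0.1, 0.1) *
                             center_spacing, n_blobs, 3)
  pts <- do.call(rbind, lapply(seq_len(n_blobs), function(b)
    matrix(stats::rnorm(3 * points_per_blob, sd = blob_sd),
           points_per_blob, 3) +
      matrix(centers[b, ], points_per_blob, 3, byrow = TRUE)))
  list(cloud = point_cloud(unname(pts), source_id = "synthetic"),
       centers = unname(centers), sd = blob_sd)
}

#' Render a point cloud as a synthetic density map
#'
#' Gaussian-kernel rendering on a bounding grid padded by five kernel
#' widths, emulating a low-resolution reconstruction; each point
#' contributes a normalized kernel scaled by its weight, so the grid
#' total approximates the total weight.
#'
#' @param cloud a [point_cloud()].
#' @param voxel_size voxel edge length (Angstrom).
#' @param kernel_width Gaussian standard deviation (Angstrom).
#' @return a [density_map()].
#' @export
make_synthetic_map <- function(cloud, voxel_size = 2, kernel_width = 3) {
  cloud <- .as_cloud(cloud)
  pad <- 5 * kernel_width
  lo <- apply(cloud$positions, 2, min) - pad
  hi <- apply(cloud$positions, 2, max) + pad
  d <- pmax(ceiling((hi - lo) / voxel_size) + 1L, 2L)
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(d[a]) - 1) * voxel_size)
  grid <- array(0, d)
  norm <- voxel_size^3 / (2 * pi * kernel_width^2)^1.5
  for (n in seq_len(n_points(cloud))) {
    gx <- exp(-(ax[[1]] - cloud$positions[n, 1])^2 / (2 * kernel_width^2))
    gy <- exp(-(ax[[2]] - cloud$positions[n, 2])^2 / (2 * kernel_width^2))
    gz <- exp(-(ax[[3]] - cloud$positions[n, 3])^2 / (2 * kernel_width^2))
    grid <- grid + cloud$weights[n] * norm * (gx %o% gy %o% gz)
  }
  density_map(grid, voxel_size = rep(voxel_size, 3), origin = lo,
              resolution_annotation = 2.355 * kernel_width)
}

#' Sample a Lennard-Jones bead fluid in a harmonic container
#'
#' Generates configurations from the Boltzmann ensemble
#' `exp(-kappa/2 sum_k ||X_k||^2 - <lambda, f(X)>)` by Hamiltonian Monte
#' Carlo with burn-in step-size adaptation. The weak harmonic container
#' (default `kappa = 0.1`) only prevents evaporation; its bias on the
#' configurational-temperature estimate is of order `kappa r^2 / |p|`
#' per pair, i.e. about 1 percent at the default settings.
#'
#' @param K number of beads.
#' @param lambdas true potential coefficients (default unit LJ, `(-4, 4)`).
#' @param kappa container spring constant.
#' @param n_sweeps HMC updates to run.
#' @param burn_in updates discarded (adaptation window).
#' @param n_steps leapfrog steps per update.
#' @param seed optional seed.
#' @param spec feature set; default LJ pair.
#' @return list with `frames` (post-burn-in K x 3 snapshots), `accept`
#'   (mean post-burn-in acceptance), `lambdas`, `kappa`.
#' @export
sample_lj_fluid <- function(K = 64, lambdas = c(-4, 4), kappa = 0.1,
                            n_sweeps = 600, burn_in = 200, n_steps = 10,
                            seed = NULL, spec = pair_potential()) {
  if (!is.null(seed)) set.seed(seed)
  ## start on a cubic lattice at roughly the pair-minimum spacing
  lj <- lambda_to_lj(lambdas)
  a0 <- if (lj$defined) 2 * lj$R_CG else 1
  side <- ceiling(K^(1 / 3))
  g <- as.matrix(expand.grid(1:side, 1:side, 1:side))[seq_len(K), ]
  X <- (g - (side + 1) / 2) * a0 + matrix(stats::rnorm(3 * K, sd = 0.01 * a0),
                                          K, 3)
  efn <- function(Xq) {
    ff <- .cg_energy_grad(Xq, spec, lambdas)
    list(energy = ff$energy + kappa / 2 * sum(Xq^2),
         grad = ff$grad + kappa * Xq)
  }
  step <- 0.02 * a0
  frames <- vector("list", n_sweeps - burn_in)
  acc <- numeric(n_sweeps)
  for (it in seq_len(n_sweeps)) {
    hm <- hmc_update(X, efn, step, n_steps)
    X <- hm$X
    acc[it] <- hm$alpha
    if (it <= burn_in) step <- step * exp(0.05 * (hm$alpha - 0.8))
    if (it > burn_in) frames[[it - burn_in]] <- X
  }
  list(frames = frames, accept = mean(acc[(burn_in + 1):n_sweeps]),
       lambdas = lambdas, kappa = kappa)
}
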