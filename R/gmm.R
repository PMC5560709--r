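## squared Euclidean distances between rows of A (N x 3) and B (K x 3);
## clamped at zero to absorb cancellation error
.sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

.logsumexp_rows <- function(M) {
  m <- apply(M, 1L, max)
  m + log(rowSums(exp(M - m)))
}

#' Log-density of a spherical 3D Gaussian
#'
#' @param x point (length-3) or N x 3 matrix of points.
#' @param mu center, length-3.
#' @param s standard deviation (same along all axes), `s > 0`.
#' @return log-density value(s): `-(3/2) log(2 pi s^2) - ||x - mu||^2 / (2 s^2)`.
#' @examples
#' log_gaussian3(c(0, 0, 0), c(0, 0, 0), 1)  # -1.5 * log(2 * pi)
#' @export
log_gaussian3 <- function(x, mu, s) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("s must be a single positive number")
  x <- if (is.matrix(x)) x else matrix(x, ncol = 3)
  mu <- as.numeric(mu)
  d2 <- rowSums(sweep(x, 2, mu)^2)
  out <- -1.5 * log(2 * pi * s^2) - d2 / (2 * s^2)
  if (length(out) == 1L) out[[1L]] else out
}

## N x K matrix of log N(x_n; X_k, s^2)
.log_component_matrix <- function(pos, X, s) {
  -1.5 * log(2 * pi * s^2) - .sqdist(pos, X) / (2 * s^2)
}

#' Marginal log-likelihood of a cloud under the equal-weight mixture
#'
#' Each point is modeled as a draw from a uniform mixture of K spherical
#' Gaussians centered at the bead positions, all with the same standard
#' deviation `s`. Weighted points contribute proportionally to their
#' weight, which is the adopted generalization for density-map input.
#'
#' @param cloud a [point_cloud()].
#' @param X K x 3 matrix of bead positions.
#' @param s model standard deviation (Angstrom), `s > 0`.
#' @return `sum_n w_n log[(1/K) sum_k N(x_n; X_k, s^2)]`, computed with
#'   log-sum-exp stabilization.
#' @export
marginal_log_likelihood <- function(cloud, X, s) {
  cloud <- .as_cloud(cloud)
  X <- .as_beads(X)
  if (!all(is.finite(X))) stop("non-finite bead positions")
  if (s <= 0) stop("s must be > 0")
  lc <- .log_component_matrix(cloud$positions, X, s)
  sum(cloud$weights * (.logsumexp_rows(lc) - log(nrow(X))))
}

.as_beads <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) != 3) stop("bead positions must be K x 3")
  storage.mode(X) <- "double"
  X
}

#' Validate an assignment vector
#'
#' Assignments encode the coarse-grained mapping: point `n` belongs to bead
#' `Z[n]`. Indices are 1-based (R convention), `1 <= Z[n] <= K`.
#' @param Z integer vector of length N.
#' @param n_points expected length.
#' @param K number of beads.
#' @return the validated integer vector (invisibly usable).
#' @export
validate_assignment <- function(Z, n_points, K) {
  Z <- as.integer(Z)
  if (length(Z) != n_points) stop("assignment length does not match cloud size")
  if (anyNA(Z) || any(Z < 1L) || any(Z > K))
    stop("assignment indices must lie in 1..K")
  Z
}

#' Augmented log-likelihood given a hard assignment
#'
#' The mixture likelihood conditioned on the assignment variables: each
#' point is scored under the Gaussian of its own bead only. Equals the
#' summary-statistic form
#' `-(3 Nw / 2) log(2 pi s^2) - (1 / 2 s^2) sum_k N_k [ ||X_k - mu_k||^2 + s_k^2 ]`
#' with `Nw` the total weight.
#'
#' @inheritParams marginal_log_likelihood
#' @param Z integer assignment vector (1-based).
#' @return scalar log-probability.
#' @export
augmented_log_likelihood <- function(cloud, X, Z, s) {
  cloud <- .as_cloud(cloud)
  X <- .as_beads(X)
  if (s <= 0) stop("s must be > 0")
  Z <- validate_assignment(Z, n_points(cloud), nrow(X))
  d2 <- rowSums((cloud$positions - X[Z, , drop = FALSE])^2)
  sum(cloud$weights * (-1.5 * log(2 * pi * s^2) - d2 / (2 * s^2)))
}

#' Per-bead summary statistics of an assignment
#'
#' Weighted counts, centers of mass and squared spreads of the points
#' assigned to each bead. Empty beads get count 0, a flagged (NA) center
#' and zero spread; they are tolerated transiently during sampling.
#'
#' @inheritParams augmented_log_likelihood
#' @param K number of beads.
#' @return list with `counts` (length K), `centers` (K x 3, NA rows for
#'   empty beads), `spreads_sq` (length K) and `empty` (logical length K).
#' @export
summarize_assignments <- function(cloud, Z, K) {
  cloud <- .as_cloud(cloud)
  K <- as.integer(K)
  Z <- validate_assignment(Z, n_points(cloud), K)
  w <- cloud$weights
  g <- factor(Z, levels = seq_len(K))
  counts <- as.numeric(tapply(w, g, sum, default = 0))
  wx <- cloud$positions * w
  sums <- rowsum(wx, g)                      # one row per occupied bead
  empty <- counts == 0
  centers <- matrix(NA_real_, K, 3)
  pres <- as.integer(rownames(sums))
  centers[pres, ] <- sums / counts[pres]
  ## spreads: weighted mean squared distance to own center
  spreads_sq <- rep(0, K)
  if (any(!empty)) {
    d2 <- rowSums((cloud$positions - centers[Z, , drop = FALSE])^2)
    ssum <- as.numeric(tapply(w * d2, g, sum, default = 0))
    spreads_sq[!empty] <- ssum[!empty] / counts[!empty]
  }
  list(counts = counts, centers = centers, spreads_sq = spreads_sq,
       empty = empty)
}

#' Goodness of fit between cloud and bead model
#'
#' The weighted sum of squared distances between each point and its
#' assigned bead, `sum_n w_n ||x_n - X_{z_n}||^2` (Angstrom squared).
#' Algebraically equal to `sum_k N_k [ ||X_k - mu_k||^2 + s_k^2 ]`.
#'
#' @inheritParams augmented_log_likelihood
#' @return scalar, >= 0.
#' @export
chi_square <- function(cloud, X, Z) {
  cloud <- .as_cloud(cloud)
  X <- .as_beads(X)
  Z <- validate_assignment(Z, n_points(cloud), nrow(X))
  sum(cloud$weights * rowSums((cloud$positions - X[Z, , drop = FALSE])^2))
}
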