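#' Pairwise inverse-power potential specification
#'
#' The coarse-grained force field is a linear expansion of pair features,
#' `E(X; lambda) = sum_l lambda_l f_l(X)` with
#' `f_l(X) = sum_{k<k'} ||X_k - X_k'||^{p_l}` for strictly negative even
#' exponents `p_l`. The default pair `(-6, -12)` realizes the attractive
#' and repulsive branches of a Lennard-Jones potential; with
#' `lambda[1] < 0 < lambda[2]` the pair energy has a unique minimum.
#'
#' @param exponents strictly negative even integers (pair-distance powers).
#' @param lambdas coefficients, one per exponent.
#' @param pair_cutoff optional distance (Angstrom) beyond which pairs are
#'   ignored (a sharp truncation; no smoothing).
#' @return object of class `pair_potential`.
#' @examples
#' sp <- pair_potential(lambdas = c(-4, 4))
#' pair_features(matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE), sp)
#' @export
pair_potential <- function(exponents = c(-6L, -12L), lambdas = rep(0, length(exponents)),
                           pair_cutoff = NULL) {
  exponents <- as.integer(exponents)
  if (length(exponents) < 1L) stop("need at least one exponent")
  if (any(exponents >= 0L) || any(exponents %% 2L != 0L))
    stop("exponents must be strictly negative even integers")
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) != length(exponents))
    stop("one lambda per exponent required")
  if (!is.null(pair_cutoff)) {
    pair_cutoff <- as.numeric(pair_cutoff)
    if (pair_cutoff <= 0) stop("pair_cutoff must be positive")
  }
  structure(list(exponents = exponents, lambdas = lambdas,
                 pair_cutoff = pair_cutoff),
            class = "pair_potential")
}

#' @export
print.pair_potential <- function(x, ...) {
  cat("pair_potential: exponents", paste(x$exponents, collapse = ", "),
      "| lambdas", paste(signif(x$lambdas, 4), collapse = ", "), "\n")
  invisible(x)
}

## rowsum() drops absent groups; scatter its result back into K rows
.accumulate_rows <- function(M, grp, K) {
  part <- rowsum(M, grp)
  out <- matrix(0, K, ncol(M))
  out[as.integer(rownames(part)), ] <- part
  out
}

## i<j pair index list for K sites
.pair_idx <- function(K) {
  i <- rep.int(seq_len(K - 1L), times = (K - 1L):1L)
  j <- sequence((K - 1L):1L, from = 2L:K)
  list(i = i, j = j)
}

## pair geometry: diffs D (P x 3), distances r, and the active-pair mask
.pair_geom <- function(X, spec) {
  K <- nrow(X)
  if (K < 2L) stop("need at least two beads for pair features")
  pr <- .pair_idx(K)
  D <- X[pr$i, , drop = FALSE] - X[pr$j, , drop = FALSE]
  r2 <- rowSums(D^2)
  if (any(r2 == 0))
    stop("coincident beads: pair distance zero makes the repulsive term diverge")
  keep <- if (is.null(spec$pair_cutoff)) rep(TRUE, length(r2)) else
    r2 <= spec$pair_cutoff^2
  list(i = pr$i[keep], j = pr$j[keep], D = D[keep, , drop = FALSE],
       r2 = r2[keep])
}

#' Pair feature values
#'
#' One value per exponent: the sum of `r^p` over all (optionally cutoff)
#' bead pairs.
#' @param X K x 3 bead positions (K >= 2, no coincident beads).
#' @param spec a [pair_potential()].
#' @return numeric vector of length `length(spec$exponents)`.
#' @export
pair_features <- function(X, spec = pair_potential()) {
  X <- .as_beads(X)
  g <- .pair_geom(X, spec)
  vapply(spec$exponents, function(p) sum(g$r2^(p / 2)), numeric(1))
}

#' Coarse-grained potential energy
#'
#' Dot product of the coefficients with the pair features,
#' `E = <lambda, f(X)>` (model units; `k_B T = 1`).
#' @inheritParams pair_features
#' @param lambdas optional override of `spec$lambdas`.
#' @return scalar energy.
#' @export
cg_energy <- function(X, spec = pair_potential(), lambdas = spec$lambdas) {
  if (all(lambdas == 0)) return(0)
  sum(lambdas * pair_features(X, spec))
}

#' Analytic gradients of the pair features
#'
#' For each exponent `p`, the gradient of `f(X) = sum r^p` with respect to
#' all bead coordinates; pair `(k, k')` at separation `r` contributes
#' `p r^{p-2} (X_k - X_k')` to bead `k` (and the negative to bead `k'`).
#' @inheritParams pair_features
#' @return list of K x 3 matrices, one per exponent.
#' @export
pair_feature_gradients <- function(X, spec = pair_potential()) {
  X <- .as_beads(X)
  K <- nrow(X)
  g <- .pair_geom(X, spec)
  grp <- c(g$i, g$j)
  lapply(spec$exponents, function(p) {
    coef <- p * g$r2^((p - 2) / 2)
    Gp <- g$D * coef
    .accumulate_rows(rbind(Gp, -Gp), grp, K)
  })
}

#' Analytic Laplacians of the pair features
#'
#' The trace of the Hessian over all 3K coordinates. In 3D the Laplacian of
#' `r^p` with respect to one endpoint is `p (p + 1) r^{p-2}`; summing both
#' endpoints, each pair contributes `2 p (p + 1) r^{p-2}`.
#' @inheritParams pair_features
#' @return numeric vector, one Laplacian per exponent.
#' @export
pair_feature_laplacians <- function(X, spec = pair_potential()) {
  X <- .as_beads(X)
  g <- .pair_geom(X, spec)
  vapply(spec$exponents,
         function(p) sum(2 * p * (p + 1) * g$r2^((p - 2) / 2)),
         numeric(1))
}

## combined energy + gradient for the default two-term case (used by HMC)
.cg_energy_grad <- function(X, spec, lambdas = spec$lambdas) {
  if (all(lambdas == 0))
    return(list(energy = 0, grad = matrix(0, nrow(X), 3)))
  K <- nrow(X)
  g <- .pair_geom(X, spec)
  grp <- c(g$i, g$j)
  E <- 0
  coef <- numeric(length(g$r2))
  for (l in seq_along(spec$exponents)) {
    p <- spec$exponents[l]
    rp <- g$r2^(p / 2)
    E <- E + lambdas[l] * sum(rp)
    coef <- coef + lambdas[l] * p * rp / g$r2
  }
  Gp <- g$D * coef
  list(energy = E, grad = .accumulate_rows(rbind(Gp, -Gp), grp, K))
}

#' Map potential coefficients to Lennard-Jones constants
#'
#' With features `r^-6` and `r^-12`, the energy
#' `lambda_1 r^-6 + lambda_2 r^-12` equals the standard form
#' `4 eps [ (sigma/r)^12 - (sigma/r)^6 ]` when `sigma = (-lambda_2 / lambda_1)^{1/6}`
#' and `eps = lambda_1^2 / (4 lambda_2)`. The bead radius is half the pair
#' distance at the energy minimum, `R_CG = 2^{1/6} sigma / 2`.
#'
#' A well-defined minimum needs `lambda_1 < 0 < lambda_2`; otherwise the
#' parameters are returned as `NA` with `defined = FALSE` (the sampler may
#' transiently visit such values, so this is not an error).
#'
#' @param lambdas length-2 numeric, coefficients of `r^-6` and `r^-12`.
#' @return list with `sigma`, `epsilon`, `R_CG` (Angstrom / model units)
#'   and logical `defined`.
#' @examples
#' lambda_to_lj(c(-4, 4))  # sigma = 1, epsilon = 1
#' @export
lambda_to_lj <- function(lambdas) {
  stopifnot(length(lambdas) == 2L)
  l1 <- lambdas[1]; l2 <- lambdas[2]
  if (!is.finite(l1) || !is.finite(l2) || l1 >= 0 || l2 <= 0)
    return(list(sigma = NA_real_, epsilon = NA_real_, R_CG = NA_real_,
                defined = FALSE))
  sigma <- (-l2 / l1)^(1 / 6)
  list(sigma = sigma, epsilon = l1^2 / (4 * l2),
       R_CG = 2^(1 / 6) * sigma / 2, defined = TRUE)
}

#' Map Lennard-Jones constants back to potential coefficients
#'
#' Inverse of [lambda_to_lj()]: `lambda_1 = -4 eps sigma^6`,
#' `lambda_2 = 4 eps sigma^12`.
#' @param sigma LJ length parameter, > 0.
#' @param epsilon well depth, > 0.
#' @return length-2 numeric vector `(lambda_1, lambda_2)`.
#' @export
lj_to_lambda <- function(sigma, epsilon) {
  if (sigma <= 0 || epsilon <= 0) stop("sigma and epsilon must be positive")
  c(-4 * epsilon * sigma^6, 4 * epsilon * sigma^12)
}
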