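#' Configuration of the Gibbs sampler
#'
#' @param K number of beads (>= 1).
#' @param n_sweeps total Gibbs sweeps.
#' @param burn_in sweeps discarded from posterior summaries; HMC step-size
#'   adaptation runs only during burn-in.
#' @param hmc_leapfrog_steps leapfrog steps per position update.
#' @param hmc_target_acceptance adaptation target in (0, 1).
#' @param lambda_update update the potential coefficients each sweep? With
#'   `FALSE` the coefficients stay clamped at zero (pure mixture-model
#'   ablation).
#' @param lambda_prior `"none"`, `"gaussian"` (ridge) or `"laplace"`
#'   (lasso) regularization of the configurational-temperature estimate.
#' @param lambda_prior_scale prior scale; `Inf` reduces the Gaussian prior
#'   to the unregularized solution.
#' @param seed integer seed; all randomness of a run flows from it.
#' @param s_floor lower bound on the model standard deviation (Angstrom),
#'   used when the fit is perfect (`chi^2 = 0`).
#' @param store_every keep an X snapshot every this many post-burn-in
#'   sweeps.
#' @return list of class `gibbs_config`.
#' @export
gibbs_config <- function(K, n_sweeps = 1000L, burn_in = 200L,
                         hmc_leapfrog_steps = 10L,
                         hmc_target_acceptance = 0.8,
                         lambda_update = TRUE,
                         lambda_prior = c("none", "gaussian", "laplace"),
                         lambda_prior_scale = Inf,
                         seed = NULL, s_floor = 1e-3,
                         store_every = 1L) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  n_sweeps <- as.integer(n_sweeps); burn_in <- as.integer(burn_in)
  if (burn_in >= n_sweeps) stop("burn_in must be smaller than n_sweeps")
  if (hmc_target_acceptance <= 0 || hmc_target_acceptance >= 1)
    stop("hmc_target_acceptance must be in (0, 1)")
  structure(list(K = K, n_sweeps = n_sweeps, burn_in = burn_in,
                 hmc_leapfrog_steps = as.integer(hmc_leapfrog_steps),
                 hmc_target_acceptance = hmc_target_acceptance,
                 lambda_update = isTRUE(lambda_update),
                 lambda_prior = match.arg(lambda_prior),
                 lambda_prior_scale = lambda_prior_scale,
                 seed = seed, s_floor = s_floor,
                 store_every = as.integer(store_every)),
            class = "gibbs_config")
}

#' Initial sampler state
#'
#' Bead positions are K distinct points drawn from the cloud by weighted
#' farthest-point seeding: the first bead with probability proportional
#' to weight, each further bead at the point maximizing weight times
#' squared distance to the nearest bead already chosen. This spreads the
#' initial beads over all well-separated clusters (plain
#' weight-proportional sampling covers c clusters with c beads only with
#' probability c!/c^c, and even k-means++-style resampling misses a
#' cluster with appreciable probability at small K).
#' Positions are jittered by 1e-3 Angstrom to break
#' exact coincidences; assignments are nearest-bead; `s` comes from the
#' resulting fit, `s^2 = chi^2 / (3 Nw)`; all potential coefficients
#' start at zero.
#'
#' @param cloud a [point_cloud()].
#' @param config a [gibbs_config()]; if `config$seed` is set the RNG is
#'   seeded here.
#' @return list with `X`, `Z`, `s`, `lambdas`, `iteration`.
#' @export
initialize_sampler <- function(cloud, config) {
  cloud <- .as_cloud(cloud)
  K <- config$K
  if (n_points(cloud) < K)
    stop("infeasible configuration: fewer points than beads")
  if (!is.null(config$seed)) set.seed(config$seed)
  idx <- integer(K)
  idx[1] <- sample.int(n_points(cloud), 1L, prob = cloud$weights)
  if (K > 1L) {
    d2min <- .sqdist(cloud$positions,
                     cloud$positions[idx[1], , drop = FALSE])[, 1]
    for (k in 2:K) {
      p <- cloud$weights * d2min
      idx[k] <- if (all(p == 0)) sample.int(n_points(cloud), 1L)
                else which.max(p)
      d2new <- .sqdist(cloud$positions,
                       cloud$positions[idx[k], , drop = FALSE])[, 1]
      d2min <- pmin(d2min, d2new)
    }
  }
  X <- cloud$positions[idx, , drop = FALSE] +
    matrix(rnorm(3 * K, sd = 1e-3), K, 3)
  Z <- max.col(-.sqdist(cloud$positions, X), ties.method = "first")
  ch <- chi_square(cloud, X, Z)
  nw <- total_weight(cloud)
  s <- max(sqrt(ch / (3 * nw)), config$s_floor)
  list(X = X, Z = Z, s = s, lambdas = NULL, iteration = 0L)
}

#' Sample the point-to-bead assignments
#'
#' Each point independently draws its bead index from the categorical
#' distribution `p_k proportional to exp(-||x_n - X_k||^2 / (2 s^2))`,
#' computed in log space. Uses the Gumbel-max trick so the whole update is
#' a single vectorized draw.
#'
#' @inheritParams marginal_log_likelihood
#' @return integer vector of length N with values in `1..K`.
#' @export
sample_assignments <- function(cloud, X, s) {
  cloud <- .as_cloud(cloud)
  X <- .as_beads(X)
  if (s <= 0) stop("s must be > 0")
  lp <- -.sqdist(cloud$positions, X) / (2 * s^2)
  g <- -log(-log(matrix(runif(length(lp)), nrow(lp), ncol(lp))))
  max.col(lp + g, ties.method = "first")
}

#' Sample the model precision
#'
#' Conjugate update: `s^-2 ~ Gamma(shape = 3 Nw / 2, rate = chi^2 / 2)`,
#' so the expected precision is `3 Nw / chi^2` (`Nw` = total weight).
#' A perfect fit (`chi^2 = 0`) returns the configured floor.
#'
#' @inheritParams augmented_log_likelihood
#' @param s_floor lower bound on the returned `s`.
#' @return sampled standard deviation `s`.
#' @export
sample_precision <- function(cloud, X, Z, s_floor = 1e-3) {
  cloud <- .as_cloud(cloud)
  ch <- chi_square(cloud, X, Z)
  nw <- total_weight(cloud)
  if (ch <= 0) return(s_floor)
  tau <- rgamma(1L, shape = 1.5 * nw, rate = ch / 2)
  max(1 / sqrt(tau), s_floor)
}

#' Posterior energy of the bead positions and its gradient
#'
#' `U(X) = (1 / 2 s^2) sum_k N_k ||X_k - mu_k||^2 + <lambda, f(X)>`:
#' a harmonic pull of each bead towards the center of mass of its assigned
#' points plus the coarse-grained pair potential. Empty beads feel only
#' the pair term.
#'
#' @param X K x 3 bead positions.
#' @param summary output of [summarize_assignments()].
#' @param s model standard deviation.
#' @param spec a [pair_potential()].
#' @param lambdas potential coefficients (default `spec$lambdas`).
#' @return list with `energy` (scalar) and `grad` (K x 3).
#' @export
posterior_energy <- function(X, summary, s, spec = pair_potential(),
                             lambdas = spec$lambdas) {
  X <- .as_beads(X)
  K <- nrow(X)
  counts <- summary$counts
  mu <- summary$centers
  occ <- !summary$empty
  dU <- matrix(0, K, 3)
  E <- 0
  if (any(occ)) {
    diff <- X[occ, , drop = FALSE] - mu[occ, , drop = FALSE]
    E <- sum(counts[occ] * rowSums(diff^2)) / (2 * s^2)
    dU[occ, ] <- counts[occ] * diff / s^2
  }
  if (K >= 2 && !all(lambdas == 0)) {
    ff <- .cg_energy_grad(X, spec, lambdas)
    E <- E + ff$energy
    dU <- dU + ff$grad
  }
  list(energy = E, grad = dU)
}

#' One Hamiltonian Monte Carlo update
#'
#' Draws fresh unit-mass momenta, integrates the Hamiltonian with the
#' leapfrog scheme and accepts or rejects on the Hamiltonian difference.
#' Non-finite energies or gradients during integration cause automatic
#' rejection.
#'
#' @param X current K x 3 positions.
#' @param energy_fn function of X returning `list(energy, grad)`.
#' @param step_size leapfrog step size.
#' @param n_steps number of leapfrog steps; 0 returns the current state as
#'   an accepted proposal.
#' @return list with `X`, `accepted` (logical) and `alpha` (acceptance
#'   probability of the proposal).
#' @export
hmc_update <- function(X, energy_fn, step_size, n_steps = 10L) {
  if (n_steps <= 0L) return(list(X = X, accepted = TRUE, alpha = 1))
  p0 <- matrix(rnorm(length(X)), nrow(X), 3)
  cur <- energy_fn(X)
  if (!is.finite(cur$energy)) stop("non-finite energy at current state")
  H0 <- cur$energy + sum(p0^2) / 2
  q <- X
  p <- p0 - step_size / 2 * cur$grad
  ok <- TRUE
  for (l in seq_len(n_steps)) {
    q <- q + step_size * p
    e <- energy_fn(q)
    if (!is.finite(e$energy) || !all(is.finite(e$grad))) { ok <- FALSE; break }
    p <- p - step_size * (if (l < n_steps) 1 else 0.5) * e$grad
  }
  if (!ok) return(list(X = X, accepted = FALSE, alpha = 0))
  H1 <- e$energy + sum(p^2) / 2
  alpha <- min(1, exp(H0 - H1))
  if (is.finite(alpha) && runif(1) < alpha)
    list(X = q, accepted = TRUE, alpha = alpha)
  else
    list(X = X, accepted = FALSE, alpha = if (is.finite(alpha)) alpha else 0)
}

#' Configurational-temperature estimate of the potential coefficients
#'
#' Solves `A lambda = b` with `A_{ll'} = <grad f_l, grad f_l'>` and
#' `b_l = Laplacian f_l`, evaluated at the single configuration `X`. This
#' sidesteps the intractable normalizing constant of the Boltzmann prior:
#' under the ensemble `exp(-<lambda, f>)` the identity
#' `E[<grad E, grad f_l>] = E[Laplacian f_l]` holds, and the per-sweep
#' solution is its one-configuration plug-in.
#'
#' A zero-centered Gaussian prior turns the solve into ridge regression in
#' closed form; a Laplace prior yields a lasso solved by coordinate
#' descent.
#'
#' @inheritParams pair_features
#' @param prior `"none"`, `"gaussian"` or `"laplace"`.
#' @param prior_scale scale of the prior; `Inf` Gaussian = no prior.
#' @return numeric vector of coefficients, one per feature.
#' @export
estimate_lambda <- function(X, spec = pair_potential(),
                            prior = c("none", "gaussian", "laplace"),
                            prior_scale = Inf) {
  prior <- match.arg(prior)
  ab <- .config_temp_Ab(X, spec)
  solve_config_temperature(ab$A, ab$b, prior = prior,
                           prior_scale = prior_scale)
}

.config_temp_Ab <- function(X, spec) {
  G <- pair_feature_gradients(X, spec)
  L <- length(G)
  A <- matrix(0, L, L)
  for (a in seq_len(L)) for (b in a:L)
    A[a, b] <- A[b, a] <- sum(G[[a]] * G[[b]])
  list(A = A, b = pair_feature_laplacians(X, spec))
}

#' Ensemble configurational-temperature estimate over many configurations
#'
#' The configurational-temperature relation holds in expectation over the
#' Boltzmann ensemble, so the moment matrices `A` and `b` are accumulated
#' over all supplied configurations and the linear system is solved once.
#' At small bead counts this removes the bias that averaging the
#' per-configuration solutions incurs (the per-sweep solve is a nonlinear
#' function of noisy moments); at large K the two estimators coincide.
#'
#' @param frames list of K x 3 configurations (e.g. post-burn-in sweeps).
#' @inheritParams estimate_lambda
#' @return coefficient vector, one per feature.
#' @export
estimate_lambda_ensemble <- function(frames, spec = pair_potential(),
                                     prior = c("none", "gaussian", "laplace"),
                                     prior_scale = Inf) {
  prior <- match.arg(prior)
  if (is.matrix(frames)) frames <- list(frames)
  L <- length(spec$exponents)
  A <- matrix(0, L, L); b <- numeric(L)
  for (X in frames) {
    ab <- .config_temp_Ab(.as_beads(X), spec)
    A <- A + ab$A; b <- b + ab$b
  }
  solve_config_temperature(A / length(frames), b / length(frames),
                           prior = prior, prior_scale = prior_scale)
}

#' Solve the configurational-temperature linear system
#'
#' Low-level solver behind [estimate_lambda()], exposed so alternative
#' feature sets (e.g. a radial harmonic feature used for validation) can
#' reuse the same machinery: supply the Gram matrix `A` of feature
#' gradients and the Laplacian vector `b`.
#'
#' @param A L x L Gram matrix of feature gradients.
#' @param b length-L vector of feature Laplacians.
#' @param prior,prior_scale see [estimate_lambda()].
#' @return length-L coefficient vector.
#' @export
solve_config_temperature <- function(A, b,
                                     prior = c("none", "gaussian", "laplace"),
                                     prior_scale = Inf) {
  prior <- match.arg(prior)
  A <- as.matrix(A); b <- as.numeric(b)
  L <- length(b)
  if (prior == "none" || (prior == "gaussian" && !is.finite(prior_scale))) {
    rc <- rcond(A)
    if (!is.finite(rc) || rc < 1e-12)
      stop("configurational-temperature system is ill-conditioned ",
           "(reciprocal condition ", signif(rc, 3),
           "); consider lambda_prior = \"gaussian\" or \"laplace\"")
    return(drop(solve(A, b)))
  }
  if (prior == "gaussian") {
    ## minimize 0.5 ||A lambda - b||^2 + 0.5 ||lambda||^2 / scale^2
    return(drop(solve(crossprod(A) + diag(L) / prior_scale^2,
                      crossprod(A, b))))
  }
  ## laplace: minimize 0.5 ||A lambda - b||^2 + ||lambda||_1 / scale
  lam <- rep(0, L)
  AtA <- crossprod(A); Atb <- drop(crossprod(A, b))
  pen <- 1 / prior_scale
  for (it in 1:500) {
    old <- lam
    for (jx in seq_len(L)) {
      rho <- Atb[jx] - sum(AtA[jx, -jx] * lam[-jx])
      lam[jx] <- sign(rho) * max(abs(rho) - pen, 0) / AtA[jx, jx]
    }
    if (max(abs(lam - old)) < 1e-12 * (1 + max(abs(lam)))) break
  }
  lam
}

#' Run the full Gibbs sampler
#'
#' Repeats the four-block sweep: assignments, precision, bead positions
#' (one HMC update of the posterior energy) and, unless clamped, the
#' configurational-temperature update of the potential coefficients.
#' The HMC step size is adapted towards the target acceptance rate during
#' burn-in (Robbins-Monro on the log step size) and frozen afterwards.
#'
#' @param cloud a [point_cloud()].
#' @param config a [gibbs_config()].
#' @param spec a [pair_potential()] defining the feature set.
#' @return object of class `bead_model`: list with the final and
#'   post-burn-in mean positions, posterior means and standard deviations
#'   of `s`, the coefficients and the derived LJ constants, the per-sweep
#'   `trace` data frame, stored `snapshots`, the final assignment and the
#'   configuration.
#' @export
run_gibbs <- function(cloud, config, spec = pair_potential()) {
  cloud <- .as_cloud(cloud)
  state <- initialize_sampler(cloud, config)   # seeds the RNG if requested
  K <- config$K
  L <- length(spec$exponents)
  lambdas <- rep(0, L)
  nw <- total_weight(cloud)
  ns <- config$n_sweeps

  summ <- summarize_assignments(cloud, state$Z, K)
  step <- 0.5 * state$s / sqrt(max(summ$counts) + 1)
  X <- state$X; Z <- state$Z; s <- state$s
  ## dual-averaging state for step-size adaptation (burn-in only)
  da <- list(mu = log(step), hbar = 0, log_eps_bar = log(step),
             gamma = 0.05, t0 = 10, kappa = 0.75)

  trace <- data.frame(iteration = seq_len(ns), s = NA_real_,
                      chi2 = NA_real_, U = NA_real_,
                      accept = NA_real_, step_size = NA_real_)
  lam_tr <- matrix(NA_real_, ns, L,
                   dimnames = list(NULL, paste0("lambda", seq_len(L))))
  lj_tr <- matrix(NA_real_, ns, 3, dimnames = list(NULL,
                  c("sigma", "epsilon", "R_CG")))
  snapshots <- list()

  for (it in seq_len(ns)) {
    Z <- sample_assignments(cloud, X, s)
    s <- sample_precision(cloud, X, Z, s_floor = config$s_floor)
    summ <- summarize_assignments(cloud, Z, K)
    efn <- function(Xq) posterior_energy(Xq, summ, s, spec, lambdas)
    if (K >= 2 || any(!summ$empty)) {
      hm <- hmc_update(X, efn, step, config$hmc_leapfrog_steps)
      X <- hm$X
      ## dual-averaging step-size adaptation during burn-in, frozen after
      if (it <= config$burn_in) {
        frac <- 1 / (it + da$t0)
        da$hbar <- (1 - frac) * da$hbar +
          frac * (config$hmc_target_acceptance - hm$alpha)
        log_eps <- da$mu - sqrt(it) / da$gamma * da$hbar
        w <- it^(-da$kappa)
        da$log_eps_bar <- w * log_eps + (1 - w) * da$log_eps_bar
        step <- exp(log_eps)
        if (it == config$burn_in) step <- exp(da$log_eps_bar)
      }
      trace$accept[it] <- hm$alpha
    } else trace$accept[it] <- 1
    if (config$lambda_update && K >= 2) {
      lambdas <- estimate_lambda(X, spec, prior = config$lambda_prior,
                                 prior_scale = config$lambda_prior_scale)
    }
    lam_tr[it, ] <- lambdas
    if (L == 2L && identical(spec$exponents, c(-6L, -12L))) {
      lj <- lambda_to_lj(lambdas)
      if (lj$defined) lj_tr[it, ] <- c(lj$sigma, lj$epsilon, lj$R_CG)
    }
    trace$s[it] <- s
    trace$chi2[it] <- chi_square(cloud, X, Z)
    trace$U[it] <- efn(X)$energy
    trace$step_size[it] <- step
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$store_every == 0L)
      snapshots[[length(snapshots) + 1L]] <- X
  }

  trace <- cbind(trace, lam_tr, lj_tr)
  post <- trace$iteration > config$burn_in
  Xmean <- if (length(snapshots)) Reduce(`+`, snapshots) / length(snapshots)
           else X
  psd <- function(v) if (sum(is.finite(v)) > 1) stats::sd(v, na.rm = TRUE)
                     else NA_real_
  model <- list(
    positions = X, positions_mean = Xmean, K = K,
    assignment = Z,
    s_mean = mean(trace$s[post]), s_sd = psd(trace$s[post]),
    lambda_mean = colMeans(lam_tr[post, , drop = FALSE]),
    lambda_sd = apply(lam_tr[post, , drop = FALSE], 2, psd),
    sigma_mean = mean(lj_tr[post, "sigma"], na.rm = TRUE),
    sigma_sd = psd(lj_tr[post, "sigma"]),
    epsilon_mean = mean(lj_tr[post, "epsilon"], na.rm = TRUE),
    epsilon_sd = psd(lj_tr[post, "epsilon"]),
    R_CG_mean = mean(lj_tr[post, "R_CG"], na.rm = TRUE),
    R_CG_sd = psd(lj_tr[post, "R_CG"]),
    trace = trace, snapshots = snapshots,
    config = config, spec = spec, source_id = cloud$source_id)
  class(model) <- "bead_model"
  model
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("bead_model: K = %d (source '%s')\n", x$K, x$source_id))
  cat(sprintf("  s     = %.4f +/- %.4f A\n", x$s_mean, x$s_sd))
  if (is.finite(x$R_CG_mean))
    cat(sprintf("  R_CG  = %.4f +/- %.4f A (sigma %.4f, epsilon %.4f)\n",
                x$R_CG_mean, x$R_CG_sd, x$sigma_mean, x$epsilon_mean))
  cat(sprintf("  sweeps = %d (burn-in %d), mean acceptance %.2f\n",
              x$config$n_sweeps, x$config$burn_in,
              mean(x$trace$accept[x$trace$iteration > x$config$burn_in],
                   na.rm = TRUE)))
  invisible(x)
}

#' Export a sampler trace as CSV
#'
#' One row per sweep with `iteration`, `s`, the coefficients, the derived
#' LJ constants, `chi2`, `U`, the acceptance probability and step size.
#' @param model a `bead_model`.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_trace_csv <- function(model, path) {
  utils::write.csv(model$trace, path, row.names = FALSE)
  invisible(path)
}
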