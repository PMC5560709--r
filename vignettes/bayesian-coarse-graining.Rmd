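---
title: "Bayesian coarse graining of biomolecular structures: model, inference and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian coarse graining of biomolecular structures: model, inference and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgbead)
```

## The model

`cgbead` reduces a structure given as $N$ weighted points $x_n$ (heavy
atoms of a PDB entry, or voxels of a thresholded cryo-EM map) to $K$
spherical beads at unknown positions $X_k$. The generative model is an
equal-weight Gaussian mixture: each point is a draw from

$$\Pr(x_n \mid X, s) = \frac{1}{K}\sum_{k=1}^K \mathcal{N}(x_n; X_k, s^2),$$

with a single standard deviation $s$ shared by all beads — beads have
equal size and occupancy by construction. Binary assignment variables
$Z_{nk}$ (one bead per point) turn the intractable product-of-sums
likelihood into a tractable augmented likelihood whose sufficient
statistics are per-bead weighted counts $N_k$, centers of mass $\mu_k$
and spreads $s_k^2$. Map-derived points carry weights (density above the
threshold, rescaled to mean 1), and every formula acquires a $w_n$
factor; atomic input is the special case $w_n = 1$. This single weighted
formulation is how the package supports atomic structures and density
maps with the same code path.

A plain mixture fit says nothing about how beads pack. The prior over
bead configurations is therefore a Boltzmann ensemble
$\Pr(X \mid \lambda) \propto \exp\{-E(X;\lambda)\}$ with a pairwise
potential expanded in inverse-power features,

$$E(X;\lambda) = \lambda_1 \sum_{k<k'} r_{kk'}^{-6} + \lambda_2 \sum_{k<k'} r_{kk'}^{-12},$$

the attractive and repulsive branches of a Lennard-Jones potential.
When $\lambda_1 < 0 < \lambda_2$ the pair energy has a unique minimum
and maps to the standard parameterization
$\sigma = (-\lambda_2/\lambda_1)^{1/6}$,
$\varepsilon = \lambda_1^2 / 4\lambda_2$, and a bead radius
$R_\mathrm{CG} = 2^{1/6}\sigma/2$ (half the pair distance at the
minimum). Energies are unitless ($k_BT \equiv 1$), so the potential of
mean force obtained later by Boltzmann inversion is on the same scale.

## Inference

`run_gibbs()` cycles four blocks per sweep, in the order
$Z \to s \to X \to \lambda$ (so the position update reacts to fresh
summaries):

1. **Assignments.** Each point draws its bead from the categorical
   distribution $p_{nk} \propto \exp\{-\lVert x_n - X_k\rVert^2/2s^2\}$,
   implemented in log space with the Gumbel-max trick — one vectorized
   draw for the whole cloud, immune to underflow when $s$ is small
   relative to inter-bead distances.
2. **Precision.** Conjugate update
   $s^{-2} \sim \mathrm{Gamma}(3N_w/2,\ \chi^2/2)$ with the second
   argument as a *rate*, so $\mathbb{E}[s^{-2}] = 3N_w/\chi^2$ as
   conjugacy requires ($N_w$ = total weight, $\chi^2$ = weighted sum of
   squared point-to-bead residuals).
3. **Positions.** One Hamiltonian Monte Carlo update of
   $U(X) = \tfrac{1}{2s^2}\sum_k N_k \lVert X_k - \mu_k\rVert^2 +
   \langle\lambda, f(X)\rangle$ with fresh unit-mass momenta, 10
   leapfrog steps by default, and a Metropolis correction. Non-finite
   energies during integration reject the proposal rather than crash.
   Empty beads (tolerated transiently) feel only the pair term.
4. **Potential coefficients.** The normalizing constant of the Boltzmann
   prior is intractable, so $\lambda$ is not sampled exactly. Instead,
   the configurational-temperature identity — under
   $\exp\{-\langle\lambda,f\rangle\}$,
   $\mathbb{E}[\langle\nabla E, \nabla f_l\rangle] =
   \mathbb{E}[\Delta f_l]$ — is solved at the current configuration:
   $A\lambda = b$ with $A_{ll'} = \langle\nabla f_l, \nabla f_{l'}\rangle$
   and $b_l = \Delta f_l$. The per-sweep solution fluctuates with $X$ but
   scatters about a stable average. Zero-centered Gaussian (ridge) or
   Laplace (lasso) priors regularize the solve when the moment system is
   ill-conditioned, which happens whenever beads are so far apart that
   the $r^{-6}/r^{-12}$ features are numerically degenerate.

Posterior summaries (means and standard deviations of $s$, $\lambda$,
$\sigma$, $\varepsilon$, $R_\mathrm{CG}$) are computed over post-burn-in
sweeps; $R_\mathrm{CG}$ is recorded only for sweeps whose $\lambda$
defines a minimum and flagged `NA` otherwise, since the coefficients are
inverse temperatures that may legitimately change sign along the chain.
Both the last configuration and the post-burn-in mean configuration are
returned; the trace holds thinned snapshots.

### Design choices that were genuinely open

* **Ensemble vs per-sweep coefficient estimation.** Averaging the
  per-sweep solutions $\hat\lambda(X_t)$ is a nonlinear function of noisy
  moments and biased at small $K$: on a 64-bead Lennard-Jones fluid
  generated at $\lambda^\ast = (-4, 4)$ the per-sweep average misses by
  ~35%, while accumulating $A$ and $b$ over sweeps and solving once
  recovers $\lambda^\ast$ to a few percent. `estimate_lambda()` implements
  the per-configuration update used inside the Gibbs sweep;
  `estimate_lambda_ensemble()` implements the moment-averaged estimator
  and is what the recovery tests assert on. At the bead counts typical of
  real assemblies (hundreds and more) the two coincide.
* **Initialization.** Beads start on cloud points chosen by weighted
  farthest-point traversal (first bead weight-proportional at random,
  then argmax of weight times squared distance to the nearest chosen
  bead), jittered by $10^{-3}$ Å. Plain weight-proportional sampling
  places at least one bead in each of $c$ well-separated clusters only
  with probability $c!/c^c$ (≈ 4% for $c=5$), which makes center
  recovery seed-dependent; farthest-point seeding removes that failure
  mode at no cost.
* **Step-size adaptation.** Dual averaging (γ = 0.05, t₀ = 10,
  κ = 0.75) on the log step size during burn-in only, frozen at the
  averaged iterate afterwards; target acceptance 0.8. Constant-gain
  stochastic approximation needed several times more burn-in to land
  within ±0.1 of the target.
* **Representative structure.** Both the final sweep and the
  post-burn-in mean are exposed; no maximum-posterior search is done.
  Note the mean is computed without relabeling beads across sweeps; on
  well-separated data labels do not switch in practice, but for highly
  symmetric inputs the mean can blur.

## Downstream analyses

* **RDF.** Pair distances pooled over frames, each bin divided by the
  ideal-gas expectation $n_\mathrm{pairs}\,V_\mathrm{shell}/V_\mathrm{ref}$.
  A finite, non-periodic bead cloud has no box volume; the reference
  volume defaults to the convex hull of the pooled configurations
  (computed by an incremental 3D hull built in-package). This makes
  $g(r)$ plateau near 1 in the bulk, with a known finite-size deficit of
  order $3r/2L$ near the boundary ($L$ = system extent) that the tests
  budget explicitly rather than hide. Default bin width 0.25 Å.
* **PMF.** $w(r) = -\ln g(r)$ ($k_BT = 1$); empty bins map to $+\infty$.
  On a Lennard-Jones fluid the PMF shows first- and second-shell
  structure while the estimated pair potential has exactly one minimum —
  the two are different objects and the package treats the PMF as a
  diagnostic only.
* **Scaling fits.** `fit_power_law()` is ordinary least squares of
  $\ln y$ on $\ln x$, for the resolution-vs-$K$ and radius-vs-$K$ laws.
* **Bead reordering.** The model is invariant under bead permutations,
  so beads are renumbered along a short open path through all beads
  (shortest-path ordering): exact Held-Karp dynamic programming up to
  $K = 12$, nearest-neighbor construction plus 2-opt refinement beyond.
  2-opt alone is not globally optimal even at $K = 8$, which is why the
  exact branch exists.
* **Map correlation.** Bead models are rendered as sums of equal-mass
  Gaussian kernels on the template grid; `cross_correlation()` is the
  Pearson correlation over (optionally thresholded) voxels, and the
  "maximum" variant scans the rendering width only — the model is
  assumed already in the map frame, rigid search is out of scope.
* **Normal modes.** Standard anisotropic network model (unit springs,
  $-\hat r\hat r^\mathsf{T}$ super-elements, cutoff 15 Å for Cα
  networks, $7R_\mathrm{CG}$ suggested for bead networks), symmetric
  eigendecomposition, six rigid-body modes identified at
  $10^{-8}$ relative eigenvalue; mode numbering is 1-based including the
  rigid modes, so "mode 7" is the first internal mode. Overlaps with a
  displacement vector are computed after least-squares rigid
  superposition (Kabsch) and are unweighted. Thin-plate-spline
  interpolation (kernel $\lVert r\rVert$ plus affine part, exact
  interpolation, one refinement step on the linear solve) carries bead
  modes onto atomic coordinates.

## Synthetic data: what a green test establishes

`make_blob_cloud()` samples the model's own generative process: Gaussian
blobs on a jittered grid, spacing/sd ≥ 5 for the "well-separated"
recovery regime (defaults: 5 blobs, 10 Å spacing, 1 Å sd, 200 points
per blob — the scale of the recovery criteria). `make_synthetic_map()`
renders a cloud at a chosen voxel size and kernel width, emulating a
low-pass-filtered reconstruction. `sample_lj_fluid()` draws bead
configurations from
$\exp\{-\kappa/2\sum\lVert X_k\rVert^2 - \langle\lambda^\ast, f\rangle\}$
by HMC; the weak container ($\kappa = 0.1$) only prevents evaporation
and biases the coefficient estimate by roughly $\kappa r^2/|p|$ per
pair, about 1% at the defaults — far below the 20% recovery tolerance.

These fixtures match the model exactly. Real crystal structures are not
mixtures of identical spherical Gaussians: atom density is inhomogeneous,
chains impose connectivity the model ignores, and EM maps carry
resolution-dependent correlated noise rather than the clean kernels used
here. Green recovery tests therefore establish the *inference machinery*
(correct conditionals, stationary HMC, unbiased moment estimation), not
the adequacy of the model for any particular biological system.

## Numerical conventions and edge cases

* All coordinates in Å, energies unitless; voxel indices 0-based in the
  world transform `world = origin + ijk * voxel_size`; the in-memory
  grid is always x,y,z-ordered regardless of the axis order in an MRC
  header.
* Likelihoods and assignment probabilities use log-sum-exp throughout.
* Coincident beads raise a singularity error in the pair features
  (initial jitter plus the repulsive term prevent them in practice).
* $\chi^2 = 0$ (perfect fit) floors $s$ at $10^{-3}$ Å instead of
  sampling a degenerate Gamma.
* `lambda_to_lj()` returns an `NA`/`defined = FALSE` marker instead of
  erroring when the coefficients define no minimum, because the sampler
  may transiently visit such values.
* The pair Laplacian of $r^p$ over both endpoints is $2p(p+1)r^{p-2}$
  (e.g. 60 per unit-distance pair for $p=-6$), validated against central
  finite differences.
* The 2×2 moment solve refuses reciprocal condition numbers below
  $10^{-12}$ without a prior, with an error message that recommends one.

## Limitations

Single bead species with uniform size and occupancy; no bonded terms,
cutoff smoothing, or physically calibrated energy scale (the potential
regularizes packing, it is not a transferable force field); $K$ is fixed
by the user, not inferred; no symmetry constraints; no rigid-body search
in the map-correlation score; the PDB reader handles the common
crystallographic records (first model, altloc resolution, water
exclusion) but not mmCIF.
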