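# cgbead

Bayesian coarse graining of large biomolecular structures and cryo-EM
density maps.

Large assemblies — hundreds of kilodaltons and up — are awkward to
simulate and to reason about atom by atom. `cgbead` reduces an atomic
structure (or a density map) to `K` interacting spherical beads and, in
a single Gibbs sampler, infers everything the reduction needs:

* the bead positions `X`,
* the atom-to-bead mapping `Z` (the *CG mapping*),
* the model precision `s` (the resolution of the bead model), and
* the coefficients `λ` of a Lennard-Jones-type pair potential that makes
  the beads pack like a fluid instead of collapsing or overlapping.

The likelihood is an equal-weight Gaussian mixture: each heavy atom
`x_n` is a draw from `(1/K) Σ_k N(x_n; X_k, s²)`. The prior over bead
configurations is a Boltzmann ensemble `exp{-λ₁ Σ r⁻⁶ - λ₂ Σ r⁻¹²}`.
Because the prior's normalizing constant is intractable, `λ` is
estimated by the configurational-temperature identity — solve
`A λ = b` with `A_{ll'} = ⟨∇f_l, ∇f_l'⟩`, `b_l = Δf_l` — instead of
being sampled. With `λ₁ < 0 < λ₂` the potential defines
`σ = (-λ₂/λ₁)^{1/6}`, `ε = λ₁²/4λ₂` and a bead radius
`R_CG = 2^{1/6} σ / 2`. Voxels of a thresholded map enter the same
machinery as weighted points, so cryo-EM reconstructions are handled by
the identical code path.

Downstream analyses from the same toolbox: radial distribution
functions with convex-hull normalization, Boltzmann-inversion potentials
of mean force, radius of gyration, power-law fits of `s(K)` and
`R_CG(K)`, traveling-salesman bead reordering, bead-model-to-map
cross-correlation, anisotropic-network normal modes with
displacement-overlap analysis, and thin-plate-spline interpolation of
bead modes onto atoms.

Who this is for: structural biologists and modelers who want
ultra-coarse bead models with a statistically explicit mapping and an
estimated packing potential, e.g. as rigid subunits in integrative
modeling or as elastic-network substrates for conformational dynamics.

## Worked example

Fit a 5-bead model to a synthetic cloud of five Gaussian blobs
(spacing 10 Å, sd 1 Å, 200 points each — the model's own generative
process, so the truth is known):

```r
library(cgbead)

fix <- make_blob_cloud(n_blobs = 5, center_spacing = 10, blob_sd = 1,
                       points_per_blob = 200, seed = 42)
cfg <- gibbs_config(K = 5, n_sweeps = 500, burn_in = 200,
                    lambda_update = FALSE, seed = 7)
model <- run_gibbs(fix$cloud, cfg)
model
#> bead_model: K = 5 (source 'synthetic')
#>   s     = 1.0189 +/- 0.0126 A
#>   sweeps = 500 (burn-in 200), mean acceptance 0.76
radius_of_gyration(model$positions_mean)
#> [1] 8.03
```

The posterior `s` recovers the generator's 1 Å blob width within 2%,
and the five bead positions land on the blob centers (the acceptance
suite checks < 0.5 Å after matching). With `lambda_update = TRUE` the
sampler additionally reports `σ`, `ε` and `R_CG` per sweep.

Estimating a pair potential from configurations alone (the
configurational-temperature estimator on a 64-bead Lennard-Jones fluid
generated at `λ* = (-4, 4)`, i.e. `σ = ε = 1`):

```r
fl  <- sample_lj_fluid(K = 64, lambdas = c(-4, 4), seed = 1,
                       n_sweeps = 700, burn_in = 300)
lam <- estimate_lambda_ensemble(fl$frames)
round(lam, 2)
#> [1] -4.27  4.20
lj <- lambda_to_lj(lam)
round(c(lj$sigma, lj$epsilon, lj$R_CG), 3)
#> [1] 0.997 1.083 0.560

r <- rdf(fl$frames, bin_width = 0.1)
r$bin_centers[which.max(r$g)]   # first RDF peak
#> [1] 1.15
2 * lj$R_CG                     # first-shell contact distance
#> [1] 1.12
```

`σ` is recovered to 0.3%, `ε` to 8%, and the RDF's first peak sits at
`2 R_CG` — first-shell neighbors touch at twice the bead radius.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/cgbead", package = "cgbead"))')
Rscript $CLI simulate --blobs 5 --points 200 --seed 3 --out sim
Rscript $CLI coarsegrain sim_cloud.pdb --beads 5 --sweeps 500 --seed 9 --out fit
Rscript $CLI scan structure.pdb --beads 25,50,100,200 --out scaling
Rscript $CLI analyze fit_beads.pdb --out rdf
Rscript $CLI modes open.pdb --delta closed.pdb --cutoff 15 --out nm
```

`coarsegrain` accepts PDB or MRC/CCP4 input (`--threshold` selects the
density cutoff for maps, `--hetero` includes HETATM records,
`--no-potential` clamps `λ = 0`); outputs are a bead PDB (reordered
along the shortest bead path), a per-sweep trace CSV and a summary JSON.
All randomness flows from `--seed`; a fixed seed reproduces runs
bit-identically.

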