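Package: cgbead
Title: Bayesian Coarse Graining of Biomolecular Structures and Density Maps
Version: 0.1.0
Authors@R:
    person("cgbead", "developers", email = "cgbead@example.org", role = c("aut", "cre"))
Description: Represents an atomic structure or a cryo-EM density map as a
    cloud of K interacting spherical beads. Bead positions, the atom-to-bead
    mapping, the model precision and the parameters of a pairwise
    Lennard-Jones-type coarse-grained potential are inferred jointly by a
    Gibbs sampler that combines categorical assignment updates, conjugate
    Gamma precision updates, Hamiltonian Monte Carlo moves of the bead
    positions and configurational-temperature estimation of the force-field
    coefficients. Includes downstream analyses: radial distribution
    functions, Boltzmann-inversion potentials of mean force, radius of
    gyration, power-law scaling fits, traveling-salesman bead reordering,
    model-to-map cross-correlation and anisotropic-network normal-mode
    overlap with thin-plate-spline mode interpolation, plus synthetic-data
    generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
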