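Package: tardyn
Title: Time-Averaged NMR Restraints for Coarse-Grained Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular dynamics of a coarse-grained C-alpha bead chain under
    NMR-derived distance and virtual-bond-angle restraints, with a numerically
    stable time-averaged restraint algorithm: flat-bottom restraint potentials
    with Gaussian walls, exponential-memory block averaging of the restrained
    quantities, and restraint-force scaling that compensates the attenuation of
    time-averaged gradients. Includes velocity-Verlet, Langevin and Berendsen
    integration, temperature replica exchange on unscaled restraint energies,
    and ensemble analysis (r^-6 averaging, upper-bound violation statistics,
    Kabsch RMSD, GDT_TS, Ward clustering), together with generators for random
    chains and synthetic restraint sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
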