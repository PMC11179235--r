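Package: nanocarve
Title: Digital Construction and Stability Analysis of Ellipsoidal Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds neutral, stoichiometric ellipsoidal nanoparticles from
    crystal structures supplied as CIF files: symmetry expansion of the unit
    cell, periodic-table-constrained element substitution, supercell
    replication, sphere and ellipsoid carving with stoichiometry
    neutralization, conjugate-gradient energy minimization over pluggable
    pair potentials (Lennard-Jones, Buckingham plus Coulomb), and a panel of
    geometric and atomistic descriptors (axis diameters, Thomsen surface
    area, ellipsoid volume, per-atom energy, coordination, common
    neighbourhood parameter, hexatic order) split into core and surface
    regions. Includes stability-driven exploration tools: fixed-volume shape
    ranking, rotation scans, and greedy crystal-growth pathway search, plus
    XYZ and LAMMPS data-file export for external force-field runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
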