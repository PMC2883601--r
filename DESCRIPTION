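Package: polwater
Title: Coarse-Grained Molecular Dynamics with a Polarizable Three-Site Water Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A self-contained coarse-grained molecular-dynamics simulator and
    analysis toolkit built around a polarizable MARTINI-style water bead: a
    neutral Lennard-Jones core carrying two constrained, oppositely charged
    satellite sites whose orientation provides orientational polarizability.
    Includes the revised charged-particle interaction-level matrix, shifted
    short-range Lennard-Jones and Coulomb kernels, a leapfrog integrator with
    SHAKE constraints and Berendsen weak coupling, seeded system builders
    (bulk water, salt solutions, water/vacuum and water/alkane slabs),
    property estimators (mass density, dipole-fluctuation dielectric constant,
    per-bead dipole statistics, radial distribution functions, surface tension
    from the pressure tensor, self-diffusion with the effective-time
    convention, charge-density/electrostatic-potential profiles), hydration
    free energies by thermodynamic integration with soft-core decoupling, and
    umbrella-sampling potentials of mean force recombined with WHAM.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
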