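Package: lvcspin
Title: Linear Vibronic Coupling Hamiltonians and Electron Spin Dynamics
    Along Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs approximate molecular and spin Hamiltonians of a
    spin-orbit-coupled metal complex along a molecular dynamics trajectory
    from linear vibronic coupling (LVC) parametrizations, projects effective
    crystal-field spin Hamiltonians in the Stevens formalism, and propagates
    the vectorised density matrix through the resulting piecewise-constant
    Hamiltonian series with a Taylor matrix-exponential-times-vector
    algorithm.  Includes Kabsch RMSD trajectory diagnostics, periodic-image
    unwrapping of solvent point charges, fixed, bisection and RMSD-adaptive
    reparametrization scheduling, Frobenius-norm error and density-matrix
    similarity metrics, and a seeded synthetic-data generator with a
    quadratic ground-truth model so the full pipeline can be exercised
    without electronic-structure software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
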