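Package: qsgwst
Title: Quasiparticle Self-Consistent GW for Molecules in Imaginary Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An all-electron, Gaussian-basis implementation of quasiparticle
    self-consistent GW (qsGW) for small closed-shell molecules. The GW
    self-energy is evaluated as a direct product of the Green's function and
    the RPA-screened Coulomb interaction on non-uniform imaginary-time grids,
    Fourier transformed to imaginary frequency by least-squares fitted
    cosine/sine transforms, and analytically continued to the real axis with
    Vidberg-Serene continued-fraction Pade approximants. The resulting static
    Hermitian exchange-correlation potential is iterated to self-consistency
    with Pulay DIIS acceleration, yielding starting-point independent
    quasiparticle ionization potentials and electron affinities. Includes a
    self-contained mean-field backend (restricted Hartree-Fock, PBE and PBE0
    with even-tempered basis sets and automatically generated auxiliary bases
    for the resolution-of-the-identity), a fixture library of small molecules,
    and a benchmark harness for starting-point and potential-construction
    consistency experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
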