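Package: ftspath
Title: Finite-Temperature String Pipeline for Field-Coupled Torsional Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for studying the competition between
    double-proton transfer and conformational transformation of a drug-like
    molecule under external electric fields. Provides a calibrated analytic
    periodic free-energy surface over two torsion angles with a linear
    electric-field coupling, restrained overdamped Langevin sampling of
    umbrella windows, the finite-temperature string method for the minimum
    free-energy path, potential-of-mean-force reconstruction by mean-force
    line integration and by WHAM, Eyring transition-state-theory rates with
    the Wigner tunneling correction, closed-form Stark and polarization
    energies for a symmetric-top rotor, and linear field-response regression
    of synthetic quantum-chemistry field scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
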