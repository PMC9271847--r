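Package: rpfold
Title: Scaffold Robustness by Random-Permutant Folding Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the robustness of a protein backbone (scaffold) to
    packing perturbations with the random-permutant (RP) method: the
    wild-type sequence is randomly permuted and repacked onto the fixed
    backbone with a clash-minimizing rotamer placer, heavy-atom native
    contact maps are computed for the wild type and each permutant, and
    coarse-grained C-alpha structure-based (Go-type) models are folded with
    Langevin dynamics.  Folding temperatures, free-energy profiles along the
    fraction of native contacts Q, folding routes, and a three-criterion
    robustness classification are derived from the simulations.  Includes a
    generator of small synthetic alpha/beta structures so that the whole
    pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
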