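Package: motorgo
Title: Structure-Based Coarse-Grained Models of Motor-Protein Mechanochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds C-alpha structure-based (Go-type) models of molecular
    motors from pairs of crystal conformations, assembles multi-basin
    Hamiltonians with switchable native-contact terms (motor head, converter
    pre/post basins, converter-head interfaces, actin interface, removable
    phosphate-mediated contacts), integrates Langevin dynamics in reduced
    units with frozen filament beads and optional constant strain forces,
    and analyses the resulting ensembles (fitted-subset RMSD distributions,
    motif distances, bimodal basin populations). Includes a deterministic
    synthetic toy-motor generator so the whole pipeline is testable without
    external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
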