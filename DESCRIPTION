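Package: mabsim
Title: Stochastic Reaction-Diffusion Simulation of Antibody Labeling of
    Cell-Surface Receptors
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact (Gillespie direct-method) stochastic simulation of the
    labeling of CD4 receptors on T cells by fluorophore-conjugated
    monoclonal antibodies.  Antibody transport is modelled as diffusive
    hops through three concentric spherical shells around the cell,
    followed by nonspecific surface adsorption and monovalent/bivalent
    receptor binding.  Includes canonical labeling and post-labeling
    (wash) scenarios, a deterministic mean-field oracle for validation,
    and a cell-population ensemble layer that propagates per-cell
    heterogeneity in receptor number and bivalent affinity into the
    mean, standard deviation and CV% of antibodies bound per cell (ABC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
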