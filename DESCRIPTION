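Package: mucosim
Title: Individual-Based Simulation of Host Epithelial Selection in Gut Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An individual-based model of two bacterial strains competing in the
    loose mucus layer on a host epithelium. Spherical cells grow by Monod
    kinetics on nutrients that diffuse in from the gut lumen above and/or the
    epithelium below, are killed by host-secreted antimicrobials, push each
    other apart as they divide, and are sloughed away above a fixed height.
    Pseudo-steady-state solute fields are computed by a finite-difference
    reaction-diffusion solver with periodic lateral boundaries. A built-in
    scenario library covers well-mixed competition, epithelial versus lumen
    selection, opposing selection from the two directions, antimicrobial
    selection, prescribed solute profiles, rare invaders, and feast-famine
    nutrient cycles, together with closed-form and two-zone ordinary
    differential equation reference models of the same competition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    readr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
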