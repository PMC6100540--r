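Package: nacscan
Title: Near-Attack-Conformation Analysis of Oxime Reactivator Docking Poses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of docking pose ensembles of oxime reactivators
    against organophosphate-inhibited cholinesterases. Computes per-pose
    attack geometry (attack distance and in-line attack angle at the adduct
    phosphorus), classifies near attack conformations (NAC), summarizes the
    percentage of low-energy poses at the NAC per reactivator, selects best
    poses, and validates redocking by ligand RMSD. Also implements the
    Ellman-assay reactivation arithmetic (intact, inhibited, and reactivated
    activities to percent reactivation with oximolysis correction and
    replicate statistics), pseudo-first-order inhibition kinetics, and the
    correlation of percent-NAC with percent reactivation including an exact
    permutation test. Ships synthetic-data generators with known ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
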