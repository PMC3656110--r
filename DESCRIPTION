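Package: prefint
Title: Preferential Interaction Coefficients and Local Protein Solvation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cosolvent effects on protein-protein association from
    solvent configurations around rigid protein structures. Computes global,
    regional and residue-resolved preferential interaction coefficients by
    two-domain solvation-shell counting at the protein van der Waals surface,
    with block-averaged standard errors; partitions a protein-protein complex
    into interface and non-interface regions and determines the interface
    distance at which solvation changes vanish; accumulates per-species 3D
    solvent occupancy grids with preferential-solvation classification,
    hydration-site detection and OpenDX export; and links solvation changes to
    association-constant shifts through Wyman linkage theory, including
    Scatchard estimation of association constants from steady-state binding
    responses. A synthetic solvent-configuration generator with brute-force
    oracles makes every estimator testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
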