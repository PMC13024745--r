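Package: gelsolv
Title: Solubilization Analytics for Drug-Ligand Small-Molecule Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the physicochemical analysis of drug-ligand co-assembled
    hydrogel systems: group-contribution Hansen solubility parameters and
    miscibility screening by solubility-parameter difference; the 1:1
    Higuchi-Connors complexation model for phase-solubility diagrams with
    stability-constant (K1:1) estimation, A_L/A_N classification and breakpoint
    detection, and a free-ligand aggregation model for negative deviation;
    sampling-corrected cumulative dissolution profiles, apparent-solubility
    enhancement ratios and supersaturation metrics; plus synthetic-data
    generators with known ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
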