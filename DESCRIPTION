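Package: apelinbias
Title: Structural and Pharmacological Diagnostics of Apelin-Receptor Ligand Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry diagnostics for molecular-dynamics trajectories of the
    apelin receptor (APLNR/APJ) and quantitative pharmacology of beta-arrestin
    recruitment assays, combined into a reproducible classifier of ligand bias.
    Includes a multi-model PDB reader/writer, Kabsch superposition and RMSD
    traces, residue-pair distance series, geometric hydrogen-bond detection,
    Shrake-Rupley solvent-accessible surface area with Monte-Carlo volume,
    ligand contact-residue tables, van der Waals steric-clash checks,
    GROMOS-style conformational clustering, operational-model (Black-Leff) and
    Hill binding/inhibition curve fitting with Bmax normalization, and a
    synthetic-data generator providing trajectories, template complexes and
    assay tables with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
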