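Package: kirdock
Title: Docking Geometry and Binding Statistics for KIR2D-HLA-C Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural comparison of two-domain killer-cell
    immunoglobulin-like receptor (KIR2D) complexes docked on peptide-HLA-C.
    Reads PDB/mmCIF coordinates, assembles role-annotated ternary complex
    models, and decomposes differences in docking geometry into hinge
    (elbow) angles, per-domain swing-twist components, centre-of-mass
    shifts along the peptide-binding groove, and domain-wise superposition
    r.m.s.d. values. Also computes residue contact footprints, Shrake-Rupley
    solvent-accessible surface areas and buried surface area of the
    receptor-ligand interface, and the accompanying binding-data
    statistics: single-antigen-bead fluorescence normalization,
    percent-of-maximum panels, tetramer/FLAG normalization, steady-state
    1:1 equilibrium dissociation constant fitting, summary-statistic
    t-tests and the Benjamini-Krieger-Yekutieli two-stage step-up false
    discovery rate procedure. Includes a ground-truthed synthetic-data
    generator so every stage is testable without external coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
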