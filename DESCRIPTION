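Package: bartraj
Title: Geometry Analysis of BAR-Domain Membrane-Bending Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory-level geometry analysis of BAR-domain dimers bending
    lipid membranes. Estimates membrane curvature by least-squares circle
    fitting of lipid phosphorus atoms in a patch beneath the dimer, detects
    helix kinks and segments Helix 2 into arm and core parts, computes the
    inter-chain angle and span time series and their Pearson correlations,
    measures solvent-accessible surface area and the pairwise interaction
    area, counts protein-lipid hydrogen bonds by residue group, and tracks
    the centripetal horizontal displacement of lipids. Includes a synthetic
    trajectory generator with closed-form ground truth for every estimator,
    readers for PDB, GRO and plain coordinate tables, and an end-to-end
    pipeline with CSV and JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
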