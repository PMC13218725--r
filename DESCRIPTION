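Package: abundmat
Title: Structure-Conditioned Substitution Matrices from Variant Abundance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis toolkit for multiplexed variant abundance data
    (VAMP-seq style scores normalised between nonsense-like 0 and
    wild-type-like 1). Reads, filters and pools per-protein variant score
    tables; computes per-residue structural descriptors (relative solvent
    accessibility, weighted contact number, secondary structure, backbone
    dihedrals) from PDB structures; builds 20x20 mean-abundance substitution
    matrices conditioned on structural environment; predicts unseen variant
    abundance by leave-one-protein-out cross-validation; classifies individual
    residue substitution profiles as buried-like or exposed-like (and
    matrix-favoured or ddG-favoured) by Gaussian resampling; and provides
    downstream matrix analyses (asymmetry, hierarchical clustering, PCA of
    concatenated substitution profiles, helix-propensity correlation,
    left-handed-helix loop analysis). A synthetic-data generator with known
    ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
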