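Package: pocketscan
Title: Ensemble Mapping of Small-Molecule Binding Pockets on GTPases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes small-molecule binding pockets across an ensemble
    of protein conformers. Provides structure ingestion and nucleotide-state
    annotation, least-squares superposition and pairwise RMSD, covariance
    principal component analysis with clustering and representative selection,
    per-residue fluctuation and cross-correlation analysis, fragment-probe
    occupancy statistics with state-differential significance testing,
    Shannon-entropy sequence conservation under full and reduced alphabets,
    Shrake-Rupley solvent accessibility with relative-exposure classification,
    compound-library descriptor and docking-score filters, and synthetic
    two-state ensemble generators for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
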