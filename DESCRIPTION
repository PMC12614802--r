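Package: protfeat
Title: Interatomic-Interaction and Compositional Feature Engineering for
    Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts multimodal machine-learning features from protein 3D
    structures: eleven interatomic-interaction and physicochemical
    descriptors (hydrogen-bond scores, van der Waals / repulsive / London
    contact counts, hydrophobicity, surface tension, accessible surface
    area), eight side-chain chemical-class frequencies, and overlapping
    k-mer (mono-, di-, tripeptide) composition over a 26-symbol amino-acid
    alphabet. Structures are read from PDB files (optionally paired with
    TRIPOS MOL2 bond records); a self-contained fixture generator builds
    ideal helices, packed toy cores, atom clouds and random sequences with
    known ground truth. Downstream utilities provide nearest-neighbour
    mutual-information feature ranking, a leakage-safe classification
    benchmark, and grouped-importance enrichment testing via the
    two-sample Kolmogorov-Smirnov statistic with Benjamini-Hochberg
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
RoxygenNote: 7.3.3
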