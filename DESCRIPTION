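Package: phosphoco
Title: Co-Occurrence Analysis of Protein Phosphorylation Across Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether pairs of protein phosphorylation sites tend to be
    modified under the same biological conditions, using one-sided Fisher's
    exact tests on binary site-by-condition profiles, and characterizes the
    significant pairs. Includes margin-preserving permutation null models at
    protein and peptide-segment level, residue co-evolution (normalized mutual
    information) and conservation scoring on species trees, information-content
    weighted annotation and kinase sharing scores, position-weight-matrix
    kinase-substrate prediction with median-score cutoffs, evaluation utilities
    (ROC/AUC, enrichment, permutation tests, distance-matched controls), and a
    synthetic-data generator that produces every pipeline input with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    methods,
    stats,
    utils,
    withr
Suggests:
    bio3d,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
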