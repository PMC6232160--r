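Package: mirhunt
Title: Homology-Based Discovery and Characterization of Plant microRNAs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in-silico pipeline for homology-based microRNA discovery in
    assembled plant transcriptomes. Candidate regions similar to known
    precursors are located with an exact affine-gap local aligner
    (k-mer-seeded for long subjects, Karlin-Altschul E-values), folded into
    stem-loop structures (ViennaRNA RNAfold or a built-in base-pair
    maximization engine) and screened with six acceptance criteria based on
    mature length, reference mismatches, arm placement, miRNA/miRNA* duplex
    mismatches, A+U content and the minimal folding energy index (MFEI).
    Accepted candidates are clustered into tentative loci, named after their
    closest reference locus, tallied by tissue, and profiled for positional
    nucleotide composition. Targets are predicted by plant-style
    complementarity scoring in two modes (expectation <= 3 and score < 4),
    intersected, classified as cleavage or translational inhibition, and
    annotated with predicted cleavage sites; target conservation across
    species sets is called at score > 50 and coverage > 50%. Precursor
    families are aligned progressively and summarized with neighbor-joining
    trees and bootstrap supports. A fully ground-truthed synthetic-data
    generator makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    igraph,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
SystemRequirements: ViennaRNA RNAfold (optional, default folding engine)
Config/testthat/edition: 3
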