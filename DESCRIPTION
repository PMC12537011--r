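Package: idrtol
Title: Mutational Tolerance and Conserved Motifs in Intrinsically Disordered Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of mutational tolerance in intrinsically disordered
    protein regions (IDRs) from protein language-model predictions. Computes
    per-residue tolerance scores as the information entropy of the softmax of
    log-likelihood-ratio (LLR) mutation profiles, classifies residues by
    structural order (pLDDT) and mutational constraint, derives per-position
    conservation scores from multiple sequence alignments (A3M, CLUSTAL,
    aligned FASTA), classifies IDRs by their overlap with experimentally
    annotated phase-separation segments, and detects conserved low-score
    sequence motifs with a bidirectional scan-intersect-merge algorithm.
    Includes a seeded synthetic-data generator that emulates the statistical
    structure of real datasets (bimodal score populations, conservation
    anticorrelated with tolerance, driver enrichment in constrained residues)
    so the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
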