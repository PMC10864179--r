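Package: msaforge
Title: Multiple Sequence Alignment Diversity, Search Orchestration,
    Complex Pairing and Coevolution Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multiple sequence alignments (MSAs) in protein
    structure prediction workflows. Reads and writes A3M and aligned-FASTA
    alignments with UniProt-style species annotation parsing; computes
    alignment diversity statistics including the effective sequence number
    (Neff), coverage and per-site depth; orchestrates staged homology-search
    pipelines (dMSA, qMSA, mMSA) over pluggable search backends with an
    early-stop rule and model-confidence MSA ranking; builds species-aware
    paired MSAs for protein complexes with stoichiometry parsing,
    pairing-budget enumeration, sequence linking, gap padding and M-score
    selection; and extracts MSA-derived coevolution features (mutual
    information and pseudolikelihood-fit 22-state Potts couplings) with
    average-product-corrected contact scores and a top-5L long-range distance
    error metric. Deterministic synthetic-data generators and mock
    scorer/predictor/backends let the complete pipeline run at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
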