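Package: leaderscan
Title: Upstream ORF Annotation and Selection Analysis in Transcript Leaders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scans transcript leaders (5' UTRs) for AUG-initiated upstream
    open reading frames and classifies them as leader-contained uORFs,
    CDS-overlapping oORFs, N-terminal extensions, or open-ended calls.
    Provides a per-leader permutation null model and an exact automaton
    dynamic program for the probability that a random leader contains each
    ORF class, cohort-level observed versus expected fractions with
    transcript-leader-length stratification and observed/expected ratio
    curves, protein-abundance comparisons between uORF- and oORF-bearing
    genes, point-substitution re-annotation of leader architectures, and a
    synthetic-cohort generator with known ground truth (including
    STN1-like fixtures) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    Matrix,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
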