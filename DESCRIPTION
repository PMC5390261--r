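Package: spcdelta
Title: Label-Free Spectral-Count Differential Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential protein-abundance analysis from label-free
    spectral counting. Implements the complete discovery workflow used in
    shotgun-proteomics comparisons of two conditions across several sample
    compartments (cell lysate, secretome, tumor xenograft): peptide-spectrum
    match filtering, parsimony protein inference with target-decoy FDR
    control, normalized spectral counts, the pseudocount-stabilized Rsc
    log2 fold-change statistic, per-protein Fisher exact tests with
    Benjamini-Hochberg correction, rule-based contaminant curation with an
    auditable exclusion ledger, functional-category summaries,
    sample-correlation clustering, and a seeded overdispersed-count
    simulator with ground truth for calibration and recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
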