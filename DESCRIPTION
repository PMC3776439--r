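Package: feedprot
Title: Feedback Protein Inference from Tandem-MS Peptide Identification Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative feedback framework for protein inference from shotgun
    proteomics peptide identification reports. Protein presence probabilities
    are estimated with a length-normalized noisy-OR model over constituent
    peptide probabilities, shared (degenerate) peptides are apportioned across
    parent proteins by the closeness of their MS/MS intensity to each parent's
    sibling-peptide average, and peptide probabilities are fed back from the
    inferred proteins until the protein and peptide lists reach a steady
    state. Includes in-silico tryptic digestion for theoretical peptide
    counts, readers for a tab-separated PSM report dialect and a pepXML
    subset, a fully synthetic proteome/report generator with known ground
    truth, and truth-based evaluation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
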