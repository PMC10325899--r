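Package: ribopause
Title: Ribosome Pause-Site Detection and Codon-Context Enrichment for
    Ribosome Profiling and eCLIP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects nucleotide-resolution ribosome pause sites from
    ribosome-footprint coverage by fitting trimmed negative binomial
    distributions per gene and replicate and combining per-position
    exceedance p-values across replicates with Fisher's method. Tests
    pause sites for differential occupancy between conditions with a
    negative binomial likelihood-ratio test and removes sites whose fold
    change merely tracks the gene-level occupancy change. Maps crosslink
    peaks and pause sites into codon space and computes positional
    amino-acid and charge-class enrichment in windows around them, with
    permutation-based significance. Scores spectral-count fractionation
    proteomics tables for replicate presence, mock-bead enrichment,
    high-confidence interactor calls and percent-ER distribution. A
    synthetic-data generator with full ground truth drives calibration
    and recovery checks for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
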