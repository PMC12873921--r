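Package: mosaicbc
Title: Barcode Sequencing Analysis for Mosaic Integrase Transgenesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies library diversity and integration multiplicity in
    mosaic zebrafish transgenesis from barcoded amplicon sequencing. Pooled
    reads are demultiplexed by 5-nt sample indexes, reverse-complemented, and
    the 15-nt random barcode is extracted between conserved anchors using a
    progressive exact/Hamming/Levenshtein search with position validation.
    Barcode variants one edit apart are collapsed into their most abundant
    parent, low-count and template-artifact barcodes are filtered, and
    abundance and diversity statistics (RPM, CV, Shannon in bits, quartile
    ratio, positional composition, sampled pairwise Hamming distance) are
    reported, together with the two-color mutual-exclusivity and hindbrain
    coverage estimators. A synthetic-data generator emulating delayed mosaic
    integration, clonal expansion and amplicon sequencing makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
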