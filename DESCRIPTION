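Package: castscreen
Title: Pooled Library Analysis for CRISPR-Associated Transposon End and
    Target-Site Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and quantification tools for pooled
    transposon-end variant screens and degenerate target-site integration
    assays of CRISPR-associated transposases (CASTs). Generates barcoded
    end-variant manifests, simulates donor-junction, barcode-coupling,
    degenerate-target and Tn7 attachment-site amplicon reads with planted
    ground truth, counts barcodes and computes wild-type-normalized
    enrichment scores, quantifies barcode uncoupling, calls integration
    distance and orientation from junction reads, builds target-site
    duplication sequence logos, fits nucleotide preference models that
    predict integration distances, scans IUPAC consensus motifs, recodes
    transposon-end open reading frames for in-frame protein tagging, and
    provides small qPCR and amplicon classification utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
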