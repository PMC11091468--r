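Package: regionmarkers
Title: Brain-Region Marker Gene Screening from Bulk RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens region-enriched and region-specific marker genes from a
    gene-by-sample RNA-seq count matrix with region labels. Computes FPKM,
    tests each region against the pooled remaining samples with a
    negative-binomial conditional exact test and Benjamini-Hochberg
    adjustment, applies a percentile-overlap screen for region-highly
    expressed genes and a fold-change screen for region-specifically
    expressed genes, selects top markers, profiles cell-type marker panels
    and receptor families across regions, and computes qPCR relative
    expression by the 2^-ddCt method. Includes a negative-binomial count
    simulator with spiked region-specific genes and truth-based recovery
    evaluation, so the whole pipeline is verifiable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
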