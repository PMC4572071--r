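Package: hlofscan
Title: Discovery and Filtering of Homozygous Loss-of-Function Variants in Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying homozygous loss-of-function (HLOF) variants in
    multi-population exome cohorts: consequence classification of stop-gain and
    frameshift variants against transcript models, a conservative artifact-filter
    cascade (relative transcript position, mapability and blacklist tracks,
    capture-kit intersection, primate ancestral alleles, multi-nucleotide codon
    changes, frameshift frame-restoration, an exact Hardy-Weinberg
    excess-homozygote test, coverage and near-fixation rules), run-of-homozygosity
    enrichment statistics, gene-set and tissue-expression enrichment summaries,
    and a mutational-burden versus extreme-phenotype regression. Includes a
    synthetic cohort generator with planted ground truth so the whole pipeline is
    testable end to end without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
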