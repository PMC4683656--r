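Package: CenCoreMap
Title: Deletion Mapping and CENH3 Enrichment Analysis of Repetitive
    Centromeres with Transposon-Display Markers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building a minimal molecular map of a highly
    repetitive centromere from retroelement junction markers. Simulates a
    CentC/CRM2/B-repeat style centromere with nested retroelement
    insertions and a pedigree of centromere-misdivision derivatives,
    performs in-silico CRM2 transposon display (restriction digestion,
    LTR-anchored selective amplification, band comparison and marker
    naming), scores marker presence across nested deletion derivatives,
    assembles markers into an N-spaced pseudocontig, maps simulated
    CENH3 ChIP-seq reads with a uniqueness-margin filter, computes
    fold enrichment relative to the genome average, and applies a
    multi-library classification rule to identify functional
    centromere-core markers, including in-silico junction-junction PCR
    genotyping of derivatives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
biocViews: Software, Epigenetics, ChIPSeq, Alignment, Coverage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
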