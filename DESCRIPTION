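Package: grbscan
Title: Classification of Gene Families into Targets of Long-Range
    Regulation Under the Genomic Regulatory Block Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies the members of a gene family into putative targets
    and non-targets of long-range (genomic regulatory block, GRB) regulation
    by integrating per-gene densities of highly conserved non-coding
    elements (HCNEs) across species pairs, CpG island length accounting,
    histone-mark tag enrichment against a bootstrap background null,
    bivalent-promoter classification in a stem cell line, and chromatin-state
    segmentation count matrices with two-way hierarchical clustering.
    Includes a fully seeded synthetic-genome generator that plants
    target-like and non-target-like genes with all derived tracks, so every
    pipeline stage is testable without genome-scale downloads, and a
    resolution rule for GRB loci that contain several candidate target
    genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
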