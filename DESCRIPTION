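Package: era3d
Title: Gene Evolutionary Age and 3D Genome Feature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating the evolutionary age of protein-coding
    genes to their positioning within 3D-genome features (topologically
    associating domains, loop anchors, boundaries) and to their expression
    across tissues. Provides phylostratigraphic age assignment from homology
    hit tables, BED-style interval pooling and coverage statistics, genome
    binning with pairwise Spearman correlation of feature densities,
    construction of intergenic open-reading-frame control sequences,
    median-of-ratios count normalization with rank-based group comparisons,
    and a seeded synthetic-data generator with planted signals so every stage
    can be tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
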