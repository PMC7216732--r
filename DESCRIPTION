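Package: methrepro
Title: DNA Methylation Reprogramming Analysis for Gametes and
    Preimplantation Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tile-based analysis of whole-genome bisulfite methylation data
    across gametes and preimplantation embryo stages. Builds non-overlapping
    100-CpG tiles and quantifies methylation of tiles and arbitrary genomic
    features under explicit coverage thresholds; segments the oocyte
    methylome into hyper- and hypomethylated domains and follows them across
    stages; screens gametic differentially methylated regions for candidate
    imprinted loci retaining intermediate methylation in blastocysts; detects
    stage-to-stage de novo methylation; clusters germline DMR trajectories;
    and correlates promoter and gene-body methylation with expression.
    Includes a seeded synthetic-methylome generator with machine-readable
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
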