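Package: genovis
Title: Server-Side Infrastructure for Genomic Visual Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Backend components for building genome-visualization and
    visual-analysis applications: parsers for common genomic text formats
    (BED, GFF3, GTF, Wiggle, BedGraph, VCF, minimal SAM), binned interval
    indices for fast region queries, multi-resolution data providers that
    switch between per-record detail and per-bin coverage summaries,
    dynamic attribute filters, linear feature-packing and Circos-style
    circular layout engines with static SVG rendering, a tool
    parameter-space sweep engine with region subsetting, a phylogenetic
    tree parser/layout/search component (Newick, PhyloXML, Nexus), seeded
    synthetic-data generators, and a command-line interface tying the
    pieces together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
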