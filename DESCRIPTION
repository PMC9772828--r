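Package: orthosplice
Title: Comparative Analysis of Core Splicing Elements in Orthologous Exons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of cassette-exon splicing between
    two species. Scores branch-point candidates in the 3' intron region
    (including the AG dinucleotide exclusion zone), scores 5' and 3' splice
    sites with maximum-entropy models, quantifies exon inclusion (PSI) from
    splice-junction read counts, maps exons between genomes through UCSC
    chain alignments to build orthologous-exon tables, and classifies
    species-exclusive alternative exons. Includes paired nonparametric
    comparison of element strengths, Hill-equation fitting of kinase
    activation curves, phosphosite-table merging and intersection analysis,
    and a seeded synthetic-data generator producing paired genomes,
    annotations, chains, junction counts, activation curves and phosphosite
    tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    minpack.lm,
    jsonlite,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    optparse
Config/testthat/edition: 3
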