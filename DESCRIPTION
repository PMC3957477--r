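Package: cisclust
Title: Composite Hox/Pbx-Meis Binding-Site Cluster Detection and
    Promoter-Set Enrichment
Version: 0.1.0
Authors@R:
    person("Morgane", "Delacroix", email = "mdelacroix@example.org",
           role = c("aut", "cre"))
Description: Position-specific scoring matrix (PSSM) scanning of
    repeat-masked DNA with exact theoretical score-distribution p-values,
    detection of composite cis-regulatory clusters in which a Hox/Pbx
    anchor site is flanked by a Meis partner site within a fixed spacing
    window, and enrichment analysis of such sites and clusters between
    labeled promoter sets against column-permutation, random-gene-set and
    Markov-background null models.  Includes a fully seeded synthetic-data
    generator (Markov backgrounds, repeat tracts, consensus-derived count
    matrices, planted clusters with ground truth) so the whole pipeline
    can be exercised and calibrated without external genomes, plus a
    hexapeptide (HX) protein-motif scanner and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
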