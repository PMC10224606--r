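Package: circscape
Title: CircRNA Catalogue Construction and Downstream Characterisation
Version: 0.1.0
Authors@R:
    person("circscape", "developers", email = "circscape@example.org",
           role = c("aut", "cre"))
Description: Tools for downstream characterisation of circular RNAs detected
    from total RNA sequencing. Merges back-spliced junction (BSJ) calls from
    multiple detection programmes into a unified catalogue, annotates splice
    status against gene models, compares circular and linear differential
    expression, tests exon-level genetic variant burden in circRNA-forming
    exons, scans circRNA and flanking-intron sequences for RNA-binding
    protein motifs with FIMO-style exact p-values, classifies circRNAs by
    flanking-intron length and inverted Alu element proximity, and builds
    circRNA:miRNA:mRNA candidate axes. Includes a seeded synthetic-data
    generator with planted, recoverable effects so the full pipeline can be
    exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
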