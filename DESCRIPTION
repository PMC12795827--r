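Package: compcis
Title: Binding-Site Localization in TF Binding Regions and Competitive
    Cis-Regulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates transcription-factor binding sites inside extended
    DAP-seq binding regions on gene 5'-regulatory sequences, links
    transcription factors to differentially expressed target genes that
    mediate enriched Gene Ontology biological processes, and calls
    candidate competitive or cooperative regulation from the mutual
    arrangement of binding sites, regulator network classes (UA/US/DA/DS)
    and effector-domain activities. Motif scanning uses position weight
    matrices with score cutoffs calibrated by an exact score-distribution
    p-value computed by dynamic programming. Includes a fully seeded
    synthetic-data generator (genome, annotation, motifs, peak sets, DEG
    lists, GO annotation, TF metadata) with a ground-truth manifest so
    every pipeline stage can be validated against planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
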