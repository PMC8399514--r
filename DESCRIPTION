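Package: cistyper
Title: Haplotype Typing, ITS Paralog Deconvolution and Haplotype Networks
    for Marker Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sequence-variation analysis of nuclear ITS and
    chloroplast intergenic-spacer alignments in closely related plant taxa:
    extraction of variable alignment columns, simple indel coding with
    homopolymer-attached indel flagging, definition and assignment of
    chlorotypes and ribotypes with main/variant/intermediate classification,
    deconvolution of superimposed paralogous ITS ribotypes from direct Sanger
    reads by reference base subtraction, Provesti and mutation-event distances,
    tie-aware minimum spanning haplotype networks, and per-population haplotype
    composition summaries with KML export. Includes reconstructions of the
    published Cistus creticus/albidus chlorotype and ribotype tables as
    fixtures and a synthetic-data generator with known truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    xml2,
    yaml,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
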