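Package: panpav
Title: Pan-Genome Presence/Absence Variation and Selection Scan Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gene presence/absence variation (PAV) in crop
    pan-genomes across domestication and improvement stages. Implements gene
    presence calling from exon coverage, core/softcore/shell/cloud pan-gene
    classification, pan- and core-genome saturation curves, windowed nucleotide
    diversity and Weir-Cockerham Fst with diversity-ratio sweep scanning,
    stage-wise favorable/unfavorable gene selection testing with Fisher's exact
    test and FDR control, PAV-SNP association with Bonferroni thresholding and
    QTL overlap, plus a synthetic-population generator with ground-truth tables
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
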