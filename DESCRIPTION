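Package: zwmarkers
Title: In Silico Evaluation of PCR Sex Markers on Avian ZW Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate intron-length-polymorphism PCR sexing markers
    (CHD1, NIPBL, SPIN type) on ZW bird genomes entirely in silico. Infers
    gene exon/intron structure by spliced mapping of mRNA onto genomic
    sequence, predicts amplicons from degenerate primers, finds gametolog or
    translocated second copies by seed-and-extend local alignment, quantifies
    Z/W intron length polymorphism, models agarose gel band resolution, and
    emits per-marker sexing verdicts. Ships a synthetic ZW genome generator
    with full ground truth and a synthetic reference fixture reproducing the
    marker geometry reported for published turaco (Musophagiformes) genome
    assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
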