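Package: clipsplice
Title: Integrative Analysis of CLIP Peaks and Alternative Splicing Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of RNA-binding-protein CLIP peak
    intervals and rMATS-style alternative-splicing event tables downstream of
    a signaling perturbation: threshold-based filtering of differential
    expression and splicing tables, strand-aware assignment of peaks to
    transcript regions (5'UTR/CDS/intron/3'UTR), splice-site and scaled
    transcript metaprofiles of peak coverage, hexamer motif enrichment against
    a dinucleotide-preserving shuffled background, cassette-exon GC and
    intron-to-exon length features with Mann-Whitney group comparisons, and
    high-confidence overlap calling between condition-unique peaks and
    differentially spliced exons. Includes a fully seeded synthetic-data
    generator (genome, annotation, peaks, splicing and expression tables with
    a ground-truth manifest) so the whole pipeline is testable without any
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
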