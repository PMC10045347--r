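Package: AREscan
Title: Antioxidant Response Element Discovery by ChIP-Supported PSSM Scanning
Version: 0.1.0
Authors@R:
    person("AREscan", "Maintainers", email = "arescan@example.org",
           role = c("aut", "cre"))
Description: Discovers putative antioxidant response elements (AREs) in gene
    regulatory regions by scanning ChIP-seq-peak-supported sequence with a
    log2-odds position-specific scoring matrix (PSSM) built from a JASPAR
    position frequency matrix. Transcript regions are extended 5000 bp
    upstream of the transcription start site, intersected with transcription
    factor ChIP-seq peaks, scanned on both strands with a relative-score
    threshold, and annotated with regulatory-segmentation state labels.
    Includes a seeded synthetic-data generator (genome, peaks, transcripts,
    segmentation, truth manifest) so the whole pipeline is testable without
    external downloads.
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
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
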