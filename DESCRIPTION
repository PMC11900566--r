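Package: m6Ashift
Title: Region-Resolved m6A Peak Classification and TSS-Anchored H3K4me3
    Summit-Shift Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies genes by the transcript region (5'UTR, CDS, 3'UTR)
    carrying N6-methyladenosine (m6A) peaks from meRIP-seq, quantifies the
    downstream shift of H3K4me3 ChIP-seq signal relative to the
    transcription start site at 10-bp resolution, and computes the overlap
    and correlation statistics linking m6A enrichment to gene expression
    and to the H3K4me3 shift. Includes a synthetic-data generator that
    emits standard-format inputs (GFF3, narrowPeak, bedGraph, expression
    tables) with a known truth manifest, so every stage of the analysis is
    testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Epigenetics, ChIPSeq, Transcription, Coverage, PeakDetection
RoxygenNote: 7.3.3
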