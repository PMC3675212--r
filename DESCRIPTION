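Package: mirhost
Title: Genome-Wide and Cross-Species Screening for Intragenic MicroRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a catalog of intragenic microRNA/host gene pairs from
    standard genome annotation. Assigns miRNA precursors to host genes by
    strand-aware containment, classifies each placement at transcript
    resolution (intron, exon, 5'-UTR, 3'-UTR, mixed), detects intragenic
    miRNA clusters and dual-host miRNAs, partitions hosts by biotype,
    screens for cross-species conserved miRNA/host co-location through
    tiered miRNA name matching and gene orthology, and overlaps mature
    miRNA seed regions with variant calls. Ships a deterministic synthetic
    annotation generator with a ground-truth manifest so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
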