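Package: arecpe
Title: ARE and CPE Motif Analysis of 3'-UTRs for Inflammatory mRNA Stability
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans 3'-UTR sequences for AU-rich elements (AREs) and cytoplasmic
    polyadenylation elements (CPEs), computes the log2 ARE:CPE dominance score,
    classifies LPS-response expression time courses as sustained or
    downregulated by their peak-normalized late expression, and calls
    RIP-seq-style binding targets from per-UTR enrichment statistics. Includes
    a fully parameterized synthetic-data generator (planted-motif UTRs,
    motif-driven decay time courses, enrichment tables with known truth) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Sequencing, MotifDiscovery, GeneRegulation, TimeCourse
RoxygenNote: 7.3.3
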