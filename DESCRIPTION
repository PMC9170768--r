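Package: OCRscan
Title: De Novo Prediction of Open Chromatin Regions from Genome Sequence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns the sequence determinants of chromatin accessibility from
    DNase-seq or ATAC-seq peak calls with a small convolutional neural
    network, converts the trained first-layer filters into position
    frequency/weight matrix motifs, and scans whole genome sequences de novo
    to emit predicted open chromatin regions as BED intervals. Includes a
    synthetic-genome generator with planted motifs and ground-truth open
    regions so the full pipeline can be exercised and validated without
    external assay data, plus threshold-sweep ROC/PR metrics and a
    threshold-merge peak caller.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
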