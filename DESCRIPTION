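Package: tfcoreg
Title: Dual Transcription-Factor Co-Regulated Target Network Inference
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers the target-gene network co-regulated by two
    transcription factors by integrating knockout differential-expression
    contrasts with ChIP-seq peak sets. Peaks are assigned to genes by a
    strand-aware, distance-classified peak-to-TSS annotation (promoter,
    proximal, putative promoter, putative distal within 10 kb);
    dual-bound, dual-downregulated genes define the co-regulated network,
    which is exported to GraphML/SIF and tested for gene-set enrichment
    by the hypergeometric tail. Supporting computations include CPM/TMM/
    RPKM count normalization and expression filtering, Venn partitioning
    of two contrasts, TSS-centered binding comparison, motif-window
    scanning, immunoglobulin clonotype dominance, and 2^-ddCt relative
    quantification, plus a synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    igraph,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
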