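Package: hicekit
Title: Scriptable Hi-C Contact Matrix Analysis from Aligned Read Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable pipeline for Hi-C chromosome conformation data:
    restriction digest indexing of a reference genome, classification and
    filtering of aligned read pairs (self-circle, dangling-end, duplicate and
    orientation-distance artifacts), genome binning and raw contact matrix
    construction, matrix balancing by iterative correction (ICE) and
    variance-stabilized wavelet denoising, A/B compartment calls by
    eigenvector analysis, TAD calling by directionality index, window-signal
    local minima with rank-sum validation, and dynamic-programming
    maximum-likelihood segmentation, integration of ChIP-seq coverage and BED
    interval tracks on the Hi-C bin grid, and gene-annotated interaction
    networks with local hypergeometric gene-set enrichment. Includes
    seed-deterministic synthetic-data generators (toy genomes, labeled read
    pairs, planted TAD/compartment matrices) so the full pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
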