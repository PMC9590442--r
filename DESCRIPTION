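Package: subspot
Title: Submicrometer Spatial Transcriptomics from Coordinate-Encoded Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for ultra-high-resolution spatial transcriptomics of the
    Seq-Scope family: parses spatial barcodes and flow-cell coordinates from
    first-round sequencing FASTQ identifiers, builds error-corrected spatial
    barcode maps and aligner whitelists, reads and writes 10x-style sparse
    digital expression matrices with coordinate sidecars and spliced/unspliced
    layers, performs spatial quality control and tissue-boundary detection,
    aggregates barcode-level counts into non-overlapping grids and overlapping
    multiscale sliding windows, clusters grid bins and projects cluster labels
    onto fine sliding-window bins, and renders cluster maps and marker-geneset
    RGB images at micrometer resolution. Includes a synthetic-data generator
    emulating coordinate-encoded reads and spatially structured counts so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Matrix,
    Biostrings,
    igraph,
    irlba,
    FNN,
    uwot,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
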