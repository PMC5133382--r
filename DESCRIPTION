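Package: metaprofiler
Title: Feature-Anchored Coverage Profiles, Heatmaps and Clustering for
    Genomic Signal Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes binned signal matrices over sets of genomic features
    from coverage tracks (bigWig, wiggle, bedGraph, BAM) or from
    genome-wide motif-density tracks built from IUPAC patterns, summarises
    them as average profiles with standard errors and 95% confidence
    intervals, clusters and sorts heatmap rows with k-means, hierarchical
    clustering or self-organizing maps, and batch-renders profile plots
    and heatmaps to PDF for any combination of signals and features. A
    plain-directory file collection with content-addressed entries and a
    precomputed signal-by-feature matrix cache support batch workflows,
    exposed both as R functions and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    Biostrings,
    ggplot2,
    patchwork,
    tibble,
    jsonlite,
    yaml,
    digest,
    mclust,
    optparse,
    stats,
    utils,
    tools,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
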