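Package: suspectr
Title: Suspect Lists of Artifact-Prone Regions from CUT&RUN Negative Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds "suspect lists" (blacklists) of artifact-prone genomic
    regions from panels of CUT&RUN negative-control experiments. Fragments
    from each control are piled into coverage tracks, peaks are called with a
    SEACR-style numeric-threshold signal-block caller, peak sets are extended
    and overlapped across samples, and regions reproducible in strictly more
    than a chosen fraction of the panel are merged into a consensus list.
    Also provides suspect-list filtering of fragments and peak sets, and the
    quality-control statistics used to validate such lists: FRIP, binned
    Spearman correlation matrices, genome-wide PCA with scree analysis,
    inter- versus intra-target distance ratios, list-versus-list comparison,
    meta-profiles, genomic annotation and low-mappability flagging. A seeded
    synthetic-data generator plants artifact regions at controllable
    prevalence to provide ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
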