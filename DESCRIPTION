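Package: chromStitch
Title: Reference-Guided Chromosome Construction, Assembly Metrics,
    Translocation Detection and Endogenous Viral Element Screening
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds chromosome-level assemblies from draft contigs guided by
    a closely related reference genome: alignment filtration, misassembly
    breakpoint classification and validation against mate-pair read
    concordance, contig splitting, ordering, gap sizing, overlap merging,
    uncovered-region recovery and gap patching, with AGP v2.1 and FASTA
    output. Also provides self-contained assembly metrics (N50, genome
    fraction, feature coverage, library statistics), interchromosomal
    translocation detection between two assemblies, a miniature translated
    (six-frame, TBLASTN-like) homology search with Karlin-Altschul
    statistics for endogenous viral element screening, and a synthetic
    genome simulator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: GenomeAssembly, Alignment, SequenceMatching, Coverage
RoxygenNote: 7.3.3
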