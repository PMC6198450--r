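Package: repkin
Title: Replication Timing and Repair Kinetics of Repetitive DNA Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how repetitive DNA elements
    (Alu, LINE-1, satellites, LTR retrotransposons) relate to genome
    organisation, replication timing and DNA double-strand-break repair.
    Provides fixed-width genomic interval binning of repeat annotations,
    GC content and read coverage (RPKM); Spearman correlation matrices
    between feature tracks with repeat-rich/poor stratification;
    "metarepetitive element" accounting that assigns multi-mapped reads
    to repeat classes; 3D image quantification of replication-timing
    colocalization (Pearson and H coefficient, S-phase substage
    classification, DNA-content staging); gammaH2AX focus segmentation
    and repair-kinetics normalisation; and synthetic-data generators with
    known ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    jsonlite
Config/testthat/edition: 3
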