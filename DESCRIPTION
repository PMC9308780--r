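Package: credyn
Title: Cis-Regulatory Element Dynamics During Primitive Endoderm Specification
Version: 0.1.0
Authors@R:
    person("Genome", "Regulation Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for multi-omic analysis of transcription-factor
    binding dynamics during a GATA6-driven epiblast-to-primitive-endoderm
    differentiation time course. Provides peak-dynamics taxonomies for
    CUT&RUN/ATAC-seq time courses (early/late x open/closed, NANOG 2 h
    redistribution clusters), nearest-TSS assignment of peaks to lineage
    genes, negative-binomial differential count testing with BH-FDR,
    FIMO-style position-weight-matrix scanning with exact p-values, motif
    density and strength comparisons between peak classes, transgene-versus-
    endogenous expression quantification from CDS/3'UTR coverage, staging of
    bulk RNA-seq samples on single-cell cluster centroids via residual PCA,
    Capture-C sliding-window differential interaction testing, and Hi-C A/B
    compartment eigenvector computation with switch calling. Includes a
    synthetic multi-omic data generator with planted ground truth so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
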