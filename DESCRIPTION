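Package: teleEnhancer
Title: Classification and Evolutionary Analysis of Tele-Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns tissue enhancers to their nearest target genes,
    classifies enhancer-gene links as proximal or tele (separated from the
    target by at least one bystander gene or exon), and contrasts the two
    enhancer classes by evolutionary constraint and regulatory signature.
    Provides two null models for link validation (DNase-hypersensitive-site
    regulatory-block containment and local synteny-breakpoint density),
    lineage-specific nucleotide divergence from three-way primate alignments
    with Jukes-Cantor correction, the Neutrality Index and McDonald-Kreitman
    test against a pseudogene neutral reference, SNP density and
    derived-allele-frequency spectra, position-weight-matrix scanning with
    linear support-vector-machine motif signatures, and hypergeometric GO
    enrichment with locus-length-matched control genes. A seeded synthetic
    data generator emits every input class on a toy genome with known
    planted parameters so the whole pipeline runs end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
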