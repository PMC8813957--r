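Package: pansv
Title: Assembly-Based Structural Variant Discovery and Pan-Genome Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for pan-genome analysis of inbred crop accessions from
    chromosome-scale assemblies. Aligns query assemblies to a reference with
    unique-anchor seeding, chains one-to-one collinear blocks, and extracts
    SNPs, small InDels, canonical and complex structural variants (SVs),
    inversions and translocations with breakpoint refinement and
    microhomology detection. Validates large InDels with a read-depth rule
    (including the insertion-to-deletion reference swap), builds an
    SV-integrated variation graph preserving the linear reference path, and
    genotypes SV sites from short reads across a population. Downstream
    modules compute windowed nucleotide diversity, selective-sweep regions
    from the wild/cultivated diversity ratio, domestication-associated and
    highly divergent SVs, SV-linked expression effects, and gene-based
    pan-genome clustering with core/dispensable classification, accumulation
    curves and Fisher set enrichment. A synthetic-data module simulates
    reference genomes, implanted variants with recorded truth, paired-end
    reads, population panels and expression tables so the whole pipeline is
    testable end-to-end against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
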