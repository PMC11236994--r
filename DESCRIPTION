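Package: eGranuleSeq
Title: Simulation and Analysis of Germ-Granule-Dependent 22G siRNA Production
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how subcompartments of the C. elegans germ granule
    shape the endogenous 22G siRNA pool. The package simulates annotated toy
    genomes and genotype-specific small-RNA sequencing libraries with known
    ground truth, quantifies antisense 22G reads per gene with the field's
    rRNA-subtracted and nonstructural-mapper normalizations, classifies genes
    into E-granule-dependent (E-class), Mutator-dependent (M-class) and
    upregulated target sets by two-fold change criteria, builds scaled
    metagene coverage profiles that detect 5'-restricted siRNA depletion,
    and quantifies condensate images via ROI-restricted Pearson
    colocalization and a three-granule contact-arrangement taxonomy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: SmallRNA, Sequencing, Coverage, Classification, Visualization
RoxygenNote: 7.3.3
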