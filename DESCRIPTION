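Package: SEhierarchy
Title: Dissecting Super-Enhancer Hierarchy from Chromatin Interactions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to dissect the internal hierarchy of super-enhancers (SEs)
    using chromatin-interaction data. Calls SEs from H3K27ac peaks by
    stitching, ranking and a geometric signal cutoff; balances raw
    intra-chromosomal Hi-C contact matrices by iterative correction (ICE);
    identifies statistically significant interactions with a
    distance-corrected binomial model under Benjamini-Hochberg FDR control;
    summarises significant interactions into per-5-kb-bin frequencies;
    computes a per-SE H-score (the maximum bin z-score) to separate
    hierarchical from non-hierarchical SEs and to label hub versus non-hub
    constituent enhancers; and provides the downstream annotation statistics
    (variant fold-enrichment with Fisher tests, CTCF binding-context
    classification, PWM motif scanning, signal profiles around anchors, and
    enhancer-promoter mapping constrained to TADs). A seedable synthetic-data
    generator produces complete desk-scale fixtures with ground-truth labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: Epigenetics, HiC, FunctionalGenomics, PeakDetection, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'SEhierarchy-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'intervals.R'
    'annotation.R'
    'hic.R'
    'hierarchy.R'
    'simulate.R'
    'pipeline.R'
    'seCaller.R'
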