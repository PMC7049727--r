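Package: HiCenclave
Title: Hierarchical Decomposition of Hi-C Contact Maps into Nested Enclaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Top-down recursive spectral bisection of per-chromosome Hi-C
    contact matrices into a partition tree of possibly non-contiguous,
    preferentially self-interacting loci clusters (enclaves). Provides
    Knight-Ruiz-style matrix balancing and Box-Cox scaling of contact
    matrices, random-walk Laplacian spectral bisection with consensus
    2-means, expansion-metric classification of bisections into split and
    strip events, identification of top and bottom enclaves and tree
    leaves, a nestedness score linearly interpolated along the tree,
    variation-of-information comparison against reference clusterings with
    a tree-matched random-clustering null and empirical P-values, overlap
    and enrichment statistics against genomic feature tracks with exact
    Poisson rate tests, DNA-loop anchor integration, and a synthetic-data
    generator that plants nested (optionally non-contiguous) interaction
    blocks on a distance-decay background.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
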