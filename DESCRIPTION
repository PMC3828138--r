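Package: mslineage
Title: Benchmarking Cell Lineage Tree Reconstruction from Microsatellite
    Mutation Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing and benchmarking cell lineage trees
    from single-cell microsatellite (short tandem repeat) repeat-count
    signatures. Provides the distance-measure families used in this setting
    (absolute, normalized absolute, Euclidean, equal-or-not, and
    maximum-likelihood divergence estimates under stepwise and multistep
    mutation models with several mutation-rate models), neighbor-joining
    with non-negative branch correction and outgroup rooting, UPGMA,
    bottom-up depth assignment for depth-free distance measures, clustering
    quality statistics on trees (quality of the largest cluster, tree
    entropy, hypergeometric clade enrichment with FDR control), depth
    separation statistics (Kolmogorov-Smirnov, normalized mean distance,
    overlap percentage), a forward simulator of lineage trees accruing
    stepwise repeat mutations, method ranking across datasets, locus
    bootstrap, and leaf-permutation significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
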