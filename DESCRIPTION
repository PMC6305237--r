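Package: ednascope
Title: Exploratory Community Ecology for eDNA Metabarcoding Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reads, validates, and analyses taxon-by-sample count tables
    produced by eDNA metabarcoding pipelines (the Anacapa tab-separated
    dialect and BIOM tables), together with per-sample metadata. Provides
    taxonomy-lineage aggregation and rank collapse, rarefaction with
    analytic taxon-accumulation curves, alpha diversity (observed
    richness, Shannon entropy) with one-way ANOVA and Tukey HSD post-hoc
    comparisons, and beta diversity: Bray-Curtis and Jaccard
    dissimilarities, principal coordinates analysis, PERMANOVA with
    exhaustive or sampled permutations plus pairwise comparisons, a
    permutation test for homogeneity of multivariate dispersions, and
    Ward.D2 hierarchical clustering. All statistics are implemented
    natively so they can be verified against brute-force oracles; a
    batch command-line interface ties the steps into reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    biomformat,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
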