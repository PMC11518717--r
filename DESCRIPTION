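Package: pitchercosm
Title: Structural and Functional Core Microbiome Analysis for Pitcher-Plant Microcosms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Downstream analysis of genus-level 16S amplicon count matrices and
    metatranscriptome hit tables from pitcher-plant (Sarracenia) microcosm
    experiments. Provides CPM and TMM normalization, alpha diversity (Chao1,
    Shannon, Pielou) with pairwise Wilcoxon comparisons, Bray-Curtis distances,
    principal coordinate analysis, PERMANOVA and PERMDISP permutation tests,
    ubiquitous/genotype-enriched/core microbiome membership with Venn partitions,
    a seeded Kruskal-Wallis + LDA effect-size screen for discriminative taxa,
    correlation co-occurrence networks with greedy community detection and
    node-role classification (hub score, within-module degree z-score,
    participation coefficient), metatranscriptome aggregation into genus and
    metaprotein abundance matrices with trait-ontology rollups, and a synthetic
    community generator with exported ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape
Config/testthat/edition: 3
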