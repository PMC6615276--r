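Package: phenomir
Title: Multiparametric Phenotypic Profiling of miRNA High-Content Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for arrayed microRNA mimic
    high-content screens in multiwell plates: seeded simulation of
    three-channel fluorescence fields with per-cell ground truth,
    blue-channel segmentation of nuclei (high-intensity class) and
    cytoplasm (medium-intensity class) with watershed splitting and seeded
    propagation, per-cell morphometric and marker-intensity features,
    percentage-of-control plate normalization into treatment-by-feature
    phenotypic profiles, hierarchical clustering with centered-correlation
    distance and average linkage (with Cluster 3.0 / Java TreeView export),
    shared predicted-target identification from TargetScan-style tables,
    hypergeometric/EASE gene-set enrichment with Benjamini-Hochberg
    correction, Venn partitions of pathway sets, and the supporting
    nonparametric statistics (2^-ddCt fold changes, exact one-tailed
    Mann-Whitney, Kruskal-Wallis with Dunn's post hoc comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    fgsea,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
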