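Package: milkbiome
Title: Compositional Analysis of Human Breast Milk 16S Bacteriome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for human-breast-milk 16S rRNA bacteriome
    analysis from OTU count tables: in-silico contamination correction using
    spiked no-template extraction controls, relative-abundance and core-taxon
    profiling, alpha diversity (Shannon, Chao1) with rarefaction and a minimum
    read-depth filter, Bray-Curtis complete-linkage community typing with
    Calinski-Harabasz and silhouette cluster-number selection, compositional
    (CLR/Aitchison) geometry with Bayesian-multiplicative zero replacement and
    lambda-scaled log-ratio biplots, genus-level co-occurrence networks from
    thresholded Pearson correlations, permutation PERMANOVA with
    Benjamini-Hochberg correction, and replicate-reproducibility regression.
    Includes a Dirichlet-multinomial cohort simulator that reproduces the
    three community-type structure (Staphylococcus-dominant, mixed,
    Streptococcus-dominant) and the spiked-control design the analyses assume,
    so every stage is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    cluster
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
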