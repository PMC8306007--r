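Package: endofungi
Title: Diversity, Preference and Co-Occurrence Analysis of Plant
    Endophytic Fungal Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for OTU-based endophytic fungal community
    surveys structured by host plant species and plant organ (stem, leaf,
    root). Provides read-count table input/output and filtering, rarefaction
    and alpha diversity (richness, Shannon, Pielou evenness) with
    Kruskal-Wallis and Welch group tests, Bray-Curtis beta diversity with
    NMDS ordination, ANOSIM and one-way PERMANOVA permutation tests,
    compositional summaries (rank aggregation with an "Others" rule, Venn
    region accounting, per-OTU differential abundance), a host/organ-fungus
    preference framework based on the bipartite specialization index d'
    with permutation-standardized effect sizes and two-dimensional
    preference (2DP) z-scores under FDR control, and Spearman co-occurrence
    networks with topology attributes, MCODE module detection, keystone
    ranking and niche-sharing node classification. Includes a
    Dirichlet-multinomial synthetic community generator that emulates the
    crossed host-by-organ study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    biomformat
Config/testthat/edition: 3
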