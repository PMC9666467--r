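Package: transectr
Title: Community Assembly, Interaction-Adjusted Beta Diversity and
    Distance Decay for Marine Microbiome Transects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the ecological mechanisms (selection, dispersal,
    drift) that assemble microbial communities along oceanographic
    transects from amplicon sequence variant (ASV) count tables, sample
    metadata and a rooted phylogeny. Implements the beta nearest taxon
    index (betaNTI) and abundance-adjusted Raup-Crick (RC-bray) null
    models with per-pair mechanism classification, SparCC compositional
    correlations and the interaction-adjusted dissimilarities TINA and
    PINA, unweighted UniFrac, phylogenetic-signal diagnostics (Mantel
    correlogram, per-ASV niches), distance-decay curve fitting and
    silhouette-guided clustering of per-family decay curves, PERMANOVA
    and ANOSIM wrappers, and a synthetic latitudinal-transect generator
    with known assembly regimes for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    ape,
    cluster,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
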