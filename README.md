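# transectr

Microbial communities along an ocean transect differ from station to
station — but *why*? transectr quantifies, for every pair of samples in
an amplicon (ASV) survey, the relative roles of the classical community
assembly mechanisms: **selection** (deterministic environmental
filtering), **dispersal** (limitation or homogenization by transport),
and **drift** (stochastic demography). It implements the two-step
phylogenetic/compositional null-model framework used in marine microbial
biogeography, together with the surrounding machinery such studies need:
interaction-adjusted beta diversity (TINA/PINA on SparCC co-occurrences),
unweighted UniFrac distance-decay curves with silhouette-guided
clustering, phylogenetic-signal diagnostics, PERMANOVA/ANOSIM screens,
and a fully synthetic transect generator with known ground truth for
end-to-end validation.

The core statistic pair, per unordered sample pair (A, B):

- **betaNTI** — the standardized deviate of the abundance-weighted beta
  mean nearest taxon distance,
  βMNTD(A,B) = ½[Σᵢ∈A f_iA · min_j∈B d_ij + Σⱼ∈B f_jB · min_i∈A d_ij],
  against a null that shuffles ASV identities across the tips of the
  cophenetic matrix. betaNTI < −2 ⇒ homogeneous selection,
  betaNTI > +2 ⇒ heterogeneous selection.
- **RC_bray** — the abundance-adjusted Raup–Crick index: the observed
  Bray–Curtis dissimilarity located within a null of probabilistic
  reassemblies (observed richness drawn by occupancy, reads filled by
  mean relative abundance), scaled to [−1, 1]. For pairs without a
  selection signal, RC_bray > +0.95 ⇒ dispersal limitation,
  RC_bray < −0.95 ⇒ homogenizing dispersal, otherwise drift.

Everything is tidyverse-native: functions take a wide count tibble
(`sample_id` + one column per ASV) first and return tibbles, pairwise
statistics come back as long pair tables, fitted objects have `tidy()`
and `glance()` methods, and each result type has an `autoplot()`.

## Worked example

Simulate a selection-structured transect (20 stations, 200 ASVs with
phylogenetically conserved thermal niches) and classify every station
pair:

```r
library(transectr)

cfg <- scenario_config(regime = "selection", n_stations = 20,
                       n_depths = 1, size_fractions = "FL",
                       n_taxa = 200, seed = 1001)
ds   <- assemble_communities(cfg)
coph <- cophenetic_distances(ds$tree)

mech <- mechanism_table(ds$counts, coph,
                        null_config(n_null = 199, seed = 1))
mechanism_fractions(mech)
#> # A tibble: 5 × 3
#>   label                   n_pairs fraction
#>   <fct>                     <int>    <dbl>
#> 1 heterogeneous_selection       0    0
#> 2 homogeneous_selection        84    0.442
#> 3 dispersal_limitation         40    0.211
#> 4 homogenizing_dispersal        0    0
#> 5 drift                        66    0.347
```

Homogeneous selection is the modal mechanism — the planted regime — and
its share falls with increasing temperature difference between stations
while dispersal limitation rises:

```r
ft <- fractions_by_temperature_difference(mech, ds$metadata, bin_width = 2)
subset(as.data.frame(ft), label == "homogeneous_selection")$fraction
#> [1] 0.6282051 0.4772727 0.2750000 0.1071429
autoplot(ft)   # stacked mechanism fractions over |dT|
```

The numbers above are what the code printed for this seed; your exact
values track the seed you pass. Other entry points follow the same
pattern: `sparcc()` + `tina()` / `pina()` for interaction-adjusted
dissimilarities, `bray_curtis()`, `unweighted_unifrac()`,
`distance_decay_curve()` + `curve_clusters()` /
`family_decay_clusters()` for decay-curve analysis, `asv_niche()` +
`mantel_correlogram()` for the phylogenetic-signal precondition,
`permanova()` / `anosim_test()` for variance partitioning, and
`run_pipeline()` to chain the stages from a YAML config with a
reproducibility manifest. See the methods vignette
(`vignettes/community-assembly-methods.Rmd`) for the models and design
choices.

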