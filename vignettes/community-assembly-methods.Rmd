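---
title: "Inferring community assembly mechanisms along ocean transects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly mechanisms along ocean transects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

transectr asks, for every pair of microbial communities sampled along an
oceanographic transect, *which ecological mechanism best explains their
difference*: deterministic environmental filtering (selection), movement
of organisms (dispersal), or stochastic demographic change (drift). It
implements the two-step null-model framework standard in microbial
ecology, the interaction-adjusted dissimilarities TINA and PINA built on
SparCC co-occurrences, and the distance-decay machinery (unweighted
UniFrac per family, loess fits, silhouette-guided clustering) used to
describe basin-scale biogeographic patterns. A synthetic transect
generator with known ground truth makes every stage testable without any
sequencing data.

This vignette explains the models, the choices we made where the
methodology left room, and what the validation suite does and does not
demonstrate. It states no empirical numbers beyond those the package's
own tests and `scripts/acceptance.R` recompute.

## The null-model framework

The framework rests on one biological premise: ecologically similar
organisms tend to be phylogenetically related, at least over short
phylogenetic distances. Given that premise (which must be *verified*, see
below), a pair of communities is interrogated in two steps.

**Step 1 — phylogenetic turnover (betaNTI).** The beta mean nearest
taxon distance is the abundance-weighted mean distance from each ASV to
its closest relative in the other sample, averaged symmetrically:

$$\beta\mathrm{MNTD}(A,B) = \tfrac12\Big[\sum_{i\in A} f_{iA}\,
\min_{j\in B} d_{ij} + \sum_{j\in B} f_{jB}\, \min_{i\in A}
d_{ij}\Big],$$

with $f$ relative abundances and $d$ cophenetic (patristic) distances.
The observed value is standardized against `n_null` (default 999)
randomizations that shuffle ASV identities across the tips of the
distance matrix, with each ASV's abundance following its label:

$$\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_\mathrm{obs} -
\overline{\beta\mathrm{MNTD}}_\mathrm{null}}{\mathrm{sd}\,
\beta\mathrm{MNTD}_\mathrm{null}}.$$

betaNTI below −2 means the communities are phylogenetically *more*
similar than chance (homogeneous selection); above +2, *less* similar
(heterogeneous selection).

Two null-design choices deserve explanation:

* **Pool scope.** By default the shuffle spans *all* ASVs of the table
  (`pool_scope = "whole_matrix"`), i.e. the regional species pool, with
  one shared permutation per null replicate — the whole dataset is
  relabelled at once. A per-pair union pool is available
  (`"pairwise"`), but we do not recommend it: when the pool is
  restricted to the taxa already present in the pair, both the observed
  and the null nearest-taxon distances are drawn from the same
  (environmentally filtered) set, and homogeneous selection becomes
  structurally undetectable.
* **Coupled labels.** Because abundances move with their labels, an ASV
  shared by both samples contributes exactly zero to every null
  replicate as well as to the observation. A consequence worth knowing:
  a sample compared with an identical copy of itself has zero null
  variance, and the pair is reported as `NA` with a warning rather than
  coerced to a value.

**Step 2 — compositional turnover (RC-bray).** Pairs whose betaNTI lies
within ±2 are passed to the abundance-adjusted Raup–Crick test. Each
sample is probabilistically reassembled `n_null` times, maintaining its
observed richness and read total: ASVs enter with probability
proportional to their occupancy across the table, each drawn ASV
receives one individual, and the remaining reads are allocated
multinomially in proportion to mean relative abundance. The observed
Bray–Curtis dissimilarity is located within the null distribution and
scaled to $[-1, 1]$ (ties count one half, so exact agreement maps to 0).
RC-bray above +0.95 indicates dispersal limitation, below −0.95
homogenizing dispersal, and anything else drift. The classification is
hierarchical: selection outranks the compositional test.

**The phylogenetic-signal precondition.** Before interpreting betaNTI,
verify that habitat preference really is phylogenetically conserved in
the data subset: `asv_niche()` computes each ASV's niche as the
abundance-weighted mean of an environmental variable over the samples
where it occurs (optionally on PCA axes of the standardized variables),
`phylo_signal_asv()` bins pairwise niche differences into 100 equal-width
cophenetic-distance bins, and `mantel_correlogram()` runs a Mantel
correlogram (default 40 equal-frequency distance classes, 999
permutations, progressive Holm correction) of habitat difference over
phylogenetic distance. Signal concentrated in the short-distance classes
is exactly what the framework requires; signal is *not* expected at deep
phylogenetic distances.

## Interaction-adjusted beta diversity

Compositional indices treat ASVs as unrelated columns. TINA instead
projects each sample through the co-occurrence structure of the whole
survey: with SparCC correlations $\rho$ rescaled to similarities
$S = (\rho + 1)/2$, each sample's relative-abundance vector $w$ becomes a
profile $u = S^\top w$, and

$$\mathrm{TINA}(A, B) = 1 - \frac{u_A \cdot u_B}{\lVert u_A\rVert\,
\lVert u_B \rVert}.$$

Two samples that share no ASVs but whose ASVs co-occur strongly across
the survey have nearly collinear profiles and hence a TINA distance near
zero while Bray–Curtis saturates at 1 — the property that makes TINA
informative about *interacting guilds* rather than shared membership.
PINA is the same construction with phylogenetic similarity
$S = 1 - d/\max(d)$. Both default to abundance weighting (consistent
with the other indices here); presence weighting is a flag.

SparCC itself estimates basis correlations from compositional counts via
log-ratio variances $t_{ij} = \mathrm{var}\log(x_i/x_j)$, solving the
sparse approximation $t_i \approx d_i\,\omega_i^2 + \sum_{j} \omega_j^2$
with iterative exclusion of the most strongly correlated pair (threshold
0.1, 10 rounds) and averaging (median) over 20 Dirichlet posterior
resamples — the original algorithm's published defaults. At least 4 ASVs are
required (the linear system is underdetermined below that) and fewer
than 10 samples triggers a warning.

## Distance decay and its clustering

Geographic distance uses the Haversine formula on a 6371-km sphere, on
station coordinates only — the decay analyses compare samples within the
same depth group, so depth does not contribute to distance.
`distance_decay_curve()` fits a loess (tricube local-linear, default
span 0.75, exact "direct" surface so that noiseless lines are
reproduced to numerical accuracy) of dissimilarity against distance and
evaluates it at equidistant grid points.

`family_decay_clusters()` reproduces the per-family analysis: families
with more than 10 ASVs and a *sequential* occurrence span of at least
10,000 km (implemented as the maximum geographic extent of a run of
consecutively occupied stations, stations ordered by latitude) are kept;
within a family, unweighted UniFrac is computed for sample pairs from
the same size fraction and depth group whose ASV overlap is strictly
between 0 and 100%; each family's distances are z-scored (so that
clustering responds to curve *shape*, not mean dissimilarity), fitted by
loess, predicted on a common grid, and clustered hierarchically (Ward
linkage) with the cluster number chosen by average silhouette width over
k = 2..10. The depth group defaults to the epipelagic/mesopelagic layer;
exact depths are an option. With exactly two eligible curves the
silhouette criterion cannot choose k and the two curves are reported as
singleton clusters.

UniFrac itself is the fraction of branch length unique to either sample
on the subtree spanned by the pair (tips absent from both and branches
rootward of the pair's most recent common ancestor are pruned first).

`permanova()` partitions the sum of squared dissimilarities explained by
one variable at a time (the variable-screening design), with p-values
from unrestricted label permutations and Benjamini–Hochberg correction
across the variable set. We authored the Gower-centring computation
rather than wrapping an existing one so that small designs (n ≤ 8) can
be tested by *complete enumeration* of permutations; the pseudo-F and
R² agree with vegan's adonis2 to numerical accuracy, which the test
suite asserts. ANOSIM and the alpha/beta-diversity primitives
(rarefaction, inverse Simpson, Bray–Curtis with total-sum +
square-root transform) delegate to vegan.

`oligotype_clusters()` z-scores each ASV's abundance profile across
samples and clusters ASVs hierarchically; because z-scores can be
negative, the Bray–Curtis input for the clustering is each ASV's
relative-abundance profile, with the z-scores reported for display.

## The abundance filter

An ASV is kept when its share of all reads strictly exceeds 0.001% *and*
it is (i) above 1% relative abundance in at least 2 samples, or (ii)
above 0.1% in at least 2% of samples, or (iii) present in at least 5% of
samples at any abundance. Clause sample counts use a ceiling ("at
least" semantics). The filter is applied to whatever table it is given;
in a multi-fraction survey we apply it per analysis subset and record
the choice in the pipeline manifest.

## The synthetic transect generator

`scenario_config()` + `generate_dataset()` emulate the study system: ~26
stations along a meridional Pacific transect, 8 depths (20–500 m,
epipelagic and upper mesopelagic), 3 size fractions, a tropical-peaked
Gaussian surface-temperature profile (29 °C peak, 2 °C polar floor,
width 20° latitude) decaying with depth toward 4 °C, a lognormal
metacommunity on a simulated birth–death phylogeny, Brownian thermal
niches (so that close relatives prefer similar temperatures), and
integer read counts at a default depth of 8000 reads per sample. Sample
weights follow

$$w_{is} \propto m_{i}^{(s)}\; e^{-(z_i - E_s)^2 / 2\sigma_w^2}\;
\ell_{is},$$

where $m^{(s)}$ mixes regional metacommunity pools through an
exponential distance kernel, the Gaussian term is the thermal niche
filter, and $\ell$ is an optional per-sample colonization lottery. The
local community is a multinomial draw of J individuals; reads are a
multinomial draw from the community, capped at J so that sequencing can
never exceed the census.

The three canonical regimes differ only in which force structures the
data:

* **neutral_drift** — no filter, unlimited dispersal, small communities
  (J = 500, sequenced exhaustively). The J-stage noise dominates.
  Capping reads at J matters here: if reads exceeded community size,
  community-level sampling noise would inflate observed Bray–Curtis
  above a null calibrated at read depth and drift would masquerade as
  dispersal limitation.
* **dispersal_limitation** — no filter, five regional pools perturbed
  by independent lognormal noise (sd 1.5) and mixed over a 500-km
  kernel, large communities (J = 10^5). Compositional turnover without
  phylogenetic structure: the RC-bray signature.
* **selection** — thermal filter of width 2 °C on a transect with a
  weak thermal contrast (2–10 °C, as in a mesopelagic section),
  communities comparable in size to the niche-qualified pool (J = 150),
  a mild colonization lottery (sd 1), an evener metacommunity (sdlog
  0.8), and niches carrying an anciently diverged cold-adapted guild (a
  deep clade of ~35% of tips displaced by −12 °C on top of the Brownian
  motion).

The selection preset deserves its longer parameter list. Homogeneous
selection is only *detectable* when ecologically equivalent taxa turn
over between samples while remaining phylogenetically clustered: if
communities are large and assembly deterministic, thermally similar
samples share essentially every ASV, the null (which preserves
shared-taxon zero distances) has nothing to judge, and every pair
degenerates to drift; if the transect spans the full 2–29 °C range,
thermally distant pairs dominate the pair set and fire the
*heterogeneous* branch instead. Moderate community size creates the
turnover, the deep thermal guild guarantees that the selected set is a
clade rather than a scatter of convergent tips (plain Brownian motion
on a 200-tip tree yields trait-extreme sets that are phylogenetically
diffuse, because extremes arise in many clades at once), and the weak
thermal contrast keeps most pairs inside the homogeneous regime — which
is also why, empirically, homogeneous selection dominates real
communities that experience similar environments over large distances.
These are generator-design choices, fixed once and documented here; the
analysis code contains no knowledge of them.

What the generator does *not* emulate: oceanographic circulation,
seasonality, sequence-level error, taxon interactions (associations in
the synthetic data arise only from shared environmental response), and
the heavy-tailed richness of real surveys (hundreds of thousands of
ASVs). Passing the recovery tests therefore shows that the inference
machinery recovers planted assembly regimes under the stated generative
model — not that real-ocean inferences are correct.

## Numerical choices and degenerate inputs

* Seeds: every stochastic routine takes an explicit seed and restores
  the caller's RNG state; the pipeline derives per-stage substreams from
  one global seed so stages reproduce in isolation.
* Rarefaction is multivariate-hypergeometric (without replacement);
  samples below the target depth are dropped and named.
* RC-bray's weighted richness draw uses the exponential-race algorithm,
  distributionally identical to successive
  probability-proportional-to-size sampling but O(p log p).
* Zero null SD (betaNTI), zero-variance UniFrac families,
  constant-profile oligotypes and zero-sum samples are reported and
  excluded, never silently coerced.
* Ties: RC-bray counts null ties as one half; equal-frequency Mantel
  classes collapse duplicated break points with a message.
* The betaNTI inner loop is compiled (C++) because the 199-replicate
  null over hundreds of pairs dominates runtime; the R-level
  `beta_mntd()` remains the reference implementation and the test suite
  asserts their exact agreement.
* Validation problem sizes (20 stations, 200 taxa, 199 nulls, 20 seeds
  for regime recovery; 100 random fixtures for the oracle checks) were
  chosen as the smallest at which the planted effects are
  unambiguous; the package defaults (999 nulls, 26 stations, 8 depths)
  remain the survey-scale values the generator emulates.

## Known limitations

* With ~200 taxa the magnitude of betaNTI is bounded in practice by the
  permutation variance of the null's nearest-taxon distances; homogeneous
  selection at |betaNTI| > 2 requires the generative ingredients listed
  above, and borderline pairs flip with the Monte-Carlo error of 199
  nulls.
* The RC-bray null conditions on occupancy-drawn richness; data whose
  richness arises from a different sampling process (e.g. pure
  multinomial reads) are systematically *more* similar than this null
  expects, so calibration statements are made against communities
  reassembled under the null's own assumptions (`resample_under_null()`).
* TINA inherits SparCC's assumptions (sparse true correlation network,
  enough samples); with fewer than ~10 samples the association matrix is
  unstable and a warning is issued.
* The pairwise pool scope for betaNTI is provided for completeness but
  weakens the test, as explained above.
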