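---
title: "Tracing microbial communities from soil to groundwater: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing microbial communities from soil to groundwater: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquacomm)
```

# The problem this package addresses

Fractured-rock aquifers host microbial communities that are seeded from the
surface: rain percolating through forested soils mobilizes cells into
seepage, which carries them into shallow perched groundwater and onward
along the hillslope flow path. Ultra-small bacteria — most prominently the
candidate phylum *Cand.* Patescibacteria — are strikingly over-represented
in groundwater relative to the soils they come from, and a large part of
their population passes even 0.2 µm filters. Three quantitative questions
follow:

1. **Where do groundwater taxa come from?** Which taxa are preferentially
   mobilized from soil into seepage, and how much of the downstream
   community is seepage-derived?
2. **What assembles the groundwater communities?** Is the pairwise turnover
   between wells driven by selection (environmental filtering), dispersal
   limitation, homogenizing dispersal, or nothing dominant?
3. **Who lives with whom, and under which hydrochemical conditions?**

`aquacomm` implements the full computational chain for these questions for
size-fractionated 16S rRNA amplicon data: qPCR-weighted merging of the
0.1 µm and 0.2 µm filter fractions, compartment-level source tracking,
phylogenetic and taxonomic null models of community assembly, Spearman
correlation profiling against hydrochemistry, and sparse positive
co-occurrence networks with stability-based edge confidence. A
synthetic-data module generates complete datasets with known ground truth,
so that every stage of the chain is verifiable without access to sequencing
archives.

# Data model

All user-facing functions take plain data frames (tibbles) and return
tibbles. An OTU table is a wide tibble whose first column is `sample_id`
and whose remaining columns are integer read counts, one per OTU. Sample
semantics (compartment soil/seepage/groundwater, site, time point, filter
fraction `F01` = 0.1 µm / `F02` = 0.2 µm / `bulk`, aquifer assemblage
HTL/HTU) live in a separate metadata table, never in the sample identifiers
themselves. Trees are `ape::phylo` objects; qPCR and hydrochemistry are
tidy per-site-and-time tables.

Rarefaction (`rarefy()`) subsamples reads **without replacement** to a
common depth (the study-scale default is 7876 reads); samples below the
target depth are dropped and reported, never padded, so every retained
sample is an equally deep draw from its community.

# Merging filter fractions with qPCR weights

Sequential filtration splits each water sample into a 0.2 µm fraction
(larger cells) and a 0.1 µm fraction of its filtrate (ultra-small cells).
Relative abundances within a fraction say nothing about the whole community
until the fractions are weighted by how much biomass each carried. With
16S rRNA gene copy numbers \(c_{F01}, c_{F02}\) (copies L⁻¹) from qPCR,

\[ w_f = \frac{c_f}{c_{F01} + c_{F02}}, \qquad
   \mathrm{merged}(o) = w_{F01}\,\mathrm{rel}_{F01}(o) + w_{F02}\,\mathrm{rel}_{F02}(o). \]

Merging is a convex combination, hence linear: aggregating merged OTU
abundances to any taxonomic rank equals merging rank-aggregated profiles,
so the order of the two operations is immaterial (we merge at OTU level to
preserve information). Copy numbers are used as-is; no 16S operon
copy-number correction is attempted. For a taxon present in both fractions,
the share of its population in the ultra-small fraction is
\(w_{F01}r_{F01}/(w_{F01}r_{F01} + w_{F02}r_{F02})\)
(`ultrasmall_share()`), and `fraction_enrichment()` reports the plain
ratio \(r_{F01}/r_{F02}\). Samples with an unusable fraction pair are
passed through as bulk with a message — never silently merged.

# Source tracking

`compartment_enrichment()` divides a taxon's mean relative abundance across
all target-compartment samples by its mean across all source samples
(unweighted arithmetic means, pooling sites and time points). A taxon
undetected in the source would yield an infinite factor; instead the result
is censored and a lower bound `target_mean / detection_floor` is reported,
with the floor defaulting to the smallest positive source abundance.

`shared_otus()` calls an OTU *detected* in a compartment if it has at least
one read in at least one sample of that compartment (low-abundance OTUs are
deliberately retained). The shared fraction
\(|A \cap B| / |\mathrm{reference}|\) is asymmetric, so the report carries
its reference side explicitly. `shared_abundance_contribution()` then asks
how much of a downstream community (optionally renormalized within a focal
taxon such as one phylum) is made of shared — e.g. seepage-derived — OTUs.
Sharing is computed directly between the two compartments named; transitive
routes through intermediate wells are not chased.

# Community assembly null models

For a pair of communities \(k, m\) with relative abundances over detected
OTUs and patristic distances \(d\), the abundance-weighted between-community
mean nearest-taxon distance is

\[ \beta\mathrm{MNTD} = \tfrac12\Big[ \sum_{i \in k} p_i \min_{j \in m} d_{ij}
   + \sum_{j \in m} p_j \min_{i \in k} d_{ji} \Big], \]

with OTUs present in both communities contributing zero nearest distance.
The null model shuffles OTU identities across the tips of the phylogeny —
jointly for both communities, over the **full OTU pool of the analyzed
table**, not just the pair — and recomputes βMNTD per shuffle. The
standardized effect size

\[ \beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{\mathrm{obs}} - \mu_{\mathrm{null}}}{\sigma_{\mathrm{null}}} \]

uses the \(n-1\) standard deviation; a degenerate null (\(\sigma = 0\),
e.g. on a star phylogeny) yields `NA` with a warning rather than ±∞.
βNTI > 2 indicates variable selection, βNTI < −2 homogeneous selection.

For stochastic pairs the rescaled Raup–Crick index on Bray–Curtis
dissimilarity discriminates dispersal regimes. Each of the (default 999)
null replicates assembles two communities that preserve each sample's
observed richness and total reads: membership is drawn without replacement
with probability proportional to each OTU's occurrence frequency across the
metacommunity (the analyzed table), every member receives one read, and the
remaining reads are assigned multinomially proportional to metacommunity
relative abundance. With \(P\) the fraction of null dissimilarities below
the observed one (ties at half weight, denominator exactly the replicate
count), \(RC_{\mathrm{bray}} = 2(P - 0.5) \in [-1, 1]\); values above 0.95
indicate dispersal limitation, below −0.95 homogenizing dispersal, and the
remainder no dominant process. `classify_assembly()` applies the two-stage
decision in that order.

`assembly_analysis()` chains the whole computation for all unordered sample
pairs: rarefaction, optional fraction merging (merged relative profiles are
converted back to integer counts at the rarefaction depth by
largest-remainder rounding so the taxonomic null can operate on reads),
both indices, and the classification. Null randomizations are regenerated
independently per pair from substreams of one run seed (the alternative —
sharing one null set across pairs — correlates the pairs' errors and saves
little). Results are plain tibbles; `autoplot()` draws the βNTI-vs-RC
plane with its decision thresholds.

# Hydrochemical correlation profiles

`spearman_profile()` computes two-sided Spearman rank correlations between
every taxon (or OTU) column and every hydrochemical parameter, with
midranks for ties and pairwise deletion of missing values. For n ≤ 9 the
p-value is exact by enumeration of all \(n!\) rank permutations — the
`stats` implementations cannot produce exact p-values under ties — and a
t approximation on \(n-2\) degrees of freedom otherwise. Significance is
assessed per test at α = 0.05 with **no** multiple-testing correction,
matching the per-test convention of the emulated analysis; a
Benjamini–Hochberg option exists but is off by default.

Taxa are grouped by the similarity of their correlation signatures with
UPGMA (average-linkage agglomeration on Euclidean distances between rows of
the coefficient matrix; undefined coefficients imputed as 0 with a
message). For ordination, non-significant coefficients are set to zero —
zero encodes "no detected association", and PCA needs a complete matrix —
the matrix is column-centred, and components come from the singular value
decomposition, with explained-variance fractions over the retained rank.

# Co-occurrence networks

The network module reduces the OTU table to OTUs with ≥ 100 reads summed
over all samples **and** presence in at least 30% of samples (the
prevalence count is a ceiling), applies a centred log-ratio transform with
pseudocount 1 (`clr = log(x+1) − mean(log(x+1))` per sample), and estimates
a sparse conditional-dependence graph by Meinshausen–Bühlmann neighborhood
selection: one L1-penalized regression per node (via glmnet) along a
log-spaced path of 20 penalties from the empirical \(\lambda_{\max}\)
(smallest penalty selecting nothing anywhere) down to
\(\lambda_{\max}/100\). Directed selections are symmetrized with the union
("or") rule; the edge coefficient is the mean of the available directed
coefficients.

Edge confidence comes from StARS: 50 subsamples of the rows without
replacement, each refit along the same path; an edge's confidence at a
penalty is its selection frequency, and the selected penalty is the densest
one whose average edge instability \(2f(1-f)\), monotonized from sparse to
dense, stays within the 0.05 threshold. The subsample size is
\(\min(\lfloor 10\sqrt{n}\rfloor, \lfloor 0.632\,n\rfloor)\): the classical
\(10\sqrt{n}\) rule presumes \(n\) in the hundreds, and subsamples must
remain a genuine fraction of the data to carry information about
reproducibility, so for small \(n\) we cap at the 1 − 1/e fraction familiar
from m-out-of-n resampling. "Edge confidence" defined as selection
frequency at the selected penalty is our documented interpretation of the
stability scheme's output.

The network is then filtered to **positive** coefficients with confidence
**strictly** above 0.5, clustered by greedy modularity maximization
(`igraph::cluster_fast_greedy`, unweighted; isolated nodes become
singletons), and summarized by degree distributions. The prevalence filter
operates on merged site-by-time communities, i.e. after fraction merging.
`neighbor_composition_test()` compares, between two node groups, the
fraction of first-degree neighbors carrying a given taxonomic label, with a
Mann–Whitney U test that is enumeration-exact for combined n ≤ 20 (midrank
ties) and tie-corrected normal beyond.

# The synthetic-data generator

`generate_scenario()` builds a complete, internally consistent dataset —
tree, taxonomy, soil/seepage/groundwater counts split into filter
fractions, qPCR totals, hydrochemistry, and a ground-truth record — under a
named assembly regime. What it emulates, and how:

* **Soil metacommunity.** Log-normal species-abundance distribution
  (`sad_sdlog = 1.5`), a realistic rank-abundance shape for amplicon data.
  The focal clade (the stand-in for the ultra-small phylum) is scaled to
  1% of the soil community — rare in soil, as observed.
* **Mobilization into seepage.** Seepage abundances are soil abundances
  multiplied by per-clade mobilization odds (focal clade × 100) and
  renormalized: preferential mobilization of the rare-in-soil clade.
* **Filter-fraction partitioning.** Every water sample's counts are split
  binomially per OTU with a clade-specific passage probability (focal 0.25,
  others 0.02): a quarter of the focal clade's population passes the 0.2 µm
  filter. qPCR fraction totals are drawn consistently with the realized
  read partition, so qPCR-weighted merging is exact by construction.
* **Groundwater along the well transect.** Each well-by-time community is
  built from a regime-specific fitness score with a niche-packing cap
  (at most `community_size = 30` resident taxa under filtering or
  homogenizing exchange; drift-driven regimes are not niche-bounded) plus a
  2% background-immigration mass from the seepage source, which keeps the
  regional pool detectable at low abundance — the "OTUs with low read
  numbers retained" property the downstream null models rely on.
  - *selection*: Gaussian niche weights
    \(\exp(-(o_i - e_w)^2 / 2b^2)\) with breadth \(b = 0.25\) on a
    standardized niche axis, wells split between environments at ±1.5, and
    a log-normal fitness lottery (sd 0.5) providing within-environment
    drift. Local fitness deliberately excludes regional abundance: under
    strong selection, niche match decides residency.
  - *homogeneous_selection*: the same machinery with one common
    off-centre environment (1.2).
  - *dispersal_limitation*: Brownian log-abundance drift along the
    transect (variance 4 per km), decorrelating wells with distance.
  - *homogenizing_dispersal*: a single shared community with small
    (sd 0.05) residual noise — high migration coupling.
  - *disjoint*: non-overlapping OTU blocks per well.
* **Niche conservatism.** Optima are clade-level base draws plus
  0.35 × standardized Brownian variation along the tree. Pure Brownian
  motion on reconstructed birth–death trees frequently leaves the selected
  niche flank phylogenetically unclustered (its mean pairwise distance
  approaches the tree-wide mean), violating the "close relatives share
  niches" premise the phylogenetic null model assumes; the hierarchical
  model guarantees it while keeping within-clade Brownian structure.
* **Hydrochemistry.** Ten parameters (DO, nitrate, sulfate, ammonium,
  sodium, potassium, magnesium, calcium, TIC, TOC) are linear responses to
  the latent environmental axis plus noise, floored at physical minima; TOC
  has no environmental slope, mirroring its mostly non-significant role.
  Ground truth stores, per clade × parameter, the sign of the deterministic
  relationship between expected clade share and the parameter across wells.
* **Planted associations.** For network scenarios, each planted edge
  carries a per-sample standard-normal latent factor added (times the
  configured effect size) to both endpoints' log-abundances; hubs
  accumulate the factors of all incident edges. This creates recoverable
  positive co-occurrence without claiming mechanism.

`scenario_preset()` couples each regime to the sampling design in which its
signal is identifiable at desk scale, together with the rarefaction depth
used in analysis:

| preset | OTUs | design | depth |
|---|---|---|---|
| selection, homogeneous_selection | 300 | 4 wells × 3 time points | 2000 |
| dispersal_limitation, homogenizing_dispersal, neutral, disjoint | 150 | 4 wells × 1 time point | 5000 |

The selection regimes need a wide regional pool relative to local richness
(the tip-shuffle null has no contrast when a sample's richness approaches
the pool size), hence more OTUs and repeated time points; the dispersal
regimes are sharpest in the compact design, where the pooled metacommunity
stays dominated by each well's drifted winners.

## What passing tests do and do not show

The generator emulates the *structure* of size-fractionated hillslope
amplicon data, not its full messiness: no chimeras or sequencing error, no
compositional overdispersion beyond log-normal noise, no 16S copy-number
variation, no temporal autocorrelation, and fraction partitioning that is
exactly binomial. Recovery of ground truth under these conditions shows the
estimators are implemented correctly and are sensitive at realistic effect
sizes; it does not certify performance on real data, where detection
limits, compositionality, and unmodeled covariance will loosen every
margin.

# Numerical choices and degenerate inputs

* Rarefaction is single-draw with a recorded seed (the emulated analysis
  subsampled once; repeated-rarefaction averaging is deliberately not
  done). All randomized routines take explicit seeds and derive
  per-component substreams; repeat runs are bit-identical.
* βNTI with a degenerate null (all distances equal) and Spearman/UPGMA
  with constant inputs return flagged `NA`s, never infinities.
* RC-bray ties count at half weight with the replicate count as the exact
  denominator, so the index is exactly ±1 when every null falls on one
  side.
* UPGMA and greedy modularity inherit the deterministic tie-handling of
  `stats::hclust` and `igraph::cluster_fast_greedy`; with continuous
  inputs, ties have measure zero.
* The prevalence threshold count uses `ceiling` ("at least 30%"), and the
  confidence cutoff is a strict inequality, so boundary cases are excluded.
* Zero-total OTU columns are allowed only transiently after subsetting;
  validation removes them with a message.

# Problem sizes used in the verification battery

The shipped tests and the acceptance script run entirely on synthetic data
at desk scale: oracle comparisons on ≤ 15-OTU instances (100 replicates),
null-model calibration with 200 trials × 199 randomizations on a 60-tip
tree, regime recovery with 199 randomizations per index over 10 seeds per
preset, network recovery at p = 60 OTUs × n = 50 samples with 50 StARS
subsamples, and source-tracking recovery over 20 seeds. These sizes were
chosen so the whole battery completes in a few minutes while every check
retains clear statistical margin; all of them scale up by changing the
corresponding arguments.

# Known limitations

* Fraction merging assumes the two qPCR measurements are comparable
  (same extraction efficiency per fraction); violations bias the weights.
* The RC-bray null treats the analyzed table as the metacommunity; with
  very few samples the occurrence-frequency weights are coarse.
* Enrichment factors with zero source means are reported as censored lower
  bounds that depend on the chosen detection floor.
* The MB/StARS network estimates conditional dependence among the
  *retained* OTUs; edges can reflect shared environmental drivers rather
  than interaction, and negative associations are discarded by design.
* Exact Spearman enumeration grows factorially; beyond n = 9 the t
  approximation is used.
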