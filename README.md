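# aquacomm

Community assembly, source tracking and co-occurrence networks for
size-fractionated groundwater microbiomes.

## The problem

Groundwater microbial communities in fractured-rock aquifers are seeded
from the surface: seepage percolating through forest soils mobilizes cells
— disproportionately ultra-small bacteria such as *Cand.* Patescibacteria,
which pass even 0.2 µm filters — into shallow wells and onward along the
hillslope flow path. Analysing such data requires a chain of
non-standard steps that `aquacomm` implements end to end for tidyverse
users:

* **Filter-fraction merging.** Each water sample is sequentially filtered
  (0.2 µm, then 0.1 µm). Whole-community profiles are reconstructed as the
  qPCR-weighted convex combination
  `merged(o) = w_F01 · rel_F01(o) + w_F02 · rel_F02(o)` with
  `w_f = copies_f / (copies_F01 + copies_F02)` from 16S rRNA gene qPCR.
* **Source tracking.** Compartment enrichment factors
  (mean target abundance / mean source abundance), shared-OTU fractions
  with an explicit reference side, and the abundance contribution of
  shared (e.g. seepage-derived) OTUs to downstream communities.
* **Community-assembly null models.** Abundance-weighted βMNTD with a
  tip-shuffling null gives βNTI = (obs − μ_null)/σ_null; the rescaled
  Raup–Crick index on Bray–Curtis, RC_bray = 2(P − 0.5) ∈ [−1, 1], uses a
  richness- and reads-preserving taxonomic null. Classification: βNTI > 2
  variable selection, βNTI < −2 homogeneous selection; otherwise
  RC_bray > 0.95 dispersal limitation, RC_bray < −0.95 homogenizing
  dispersal, else no dominant process.
* **Hydrochemical profiling.** Two-sided Spearman correlations
  (permutation-exact p for n ≤ 9, midrank ties), UPGMA clustering of
  correlation signatures, and PCA of significant coefficients.
* **Co-occurrence networks.** ≥100-read / ≥30%-prevalence filtering, CLR
  transform, Meinshausen–Bühlmann neighborhood selection over a 20-point
  lambda path, StARS stability selection (50 subsamples) yielding per-edge
  confidence, filtering to positive edges with confidence > 0.5, greedy
  modularity clustering, degree distributions, and exact Mann–Whitney
  comparisons of neighbor composition.
* **Synthetic data.** `generate_scenario()` builds complete datasets
  (tree, fractionated counts, qPCR, hydrochemistry, taxonomy) under named
  assembly regimes with recorded ground truth, so every stage is testable
  without sequence archives.

All user-facing functions take data frames first and return tibbles;
result objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a hillslope study under dispersal limitation, merge the filter
fractions with qPCR weights, rank taxa by soil-to-seepage enrichment, and
classify the assembly process for every well pair:

```r
library(aquacomm)
library(dplyr)

sc <- generate_scenario(scenario_config(seed = 1, regime = "dispersal_limitation"))
bundle <- sc$bundle

merged <- merge_sample_fractions(bundle$counts, bundle$metadata, bundle$qpcr)
attr(merged, "weights")[11:14, ]
#> # A tibble: 4 × 5
#>   sample_id site  time_point  w_f01 w_f02
#>   <chr>     <chr> <chr>       <dbl> <dbl>
#> 1 H13_T1    H13   T1         0.0847 0.915
#> 2 H31_T1    H31   T1         0.0511 0.949
#> 3 H41_T1    H41   T1         0.0263 0.974
#> 4 H51_T1    H51   T1         0.0287 0.971
```

Roughly 3–8% of the 16S gene copies of each groundwater sample sit in the
ultra-small (0.1 µm) fraction; the merged rows each sum to 1.

```r
soil_ids <- bundle$metadata$sample_id[bundle$metadata$compartment == "soil"]
seep_ids <- paste(unique(bundle$metadata$site[bundle$metadata$compartment == "seepage"]),
                  "T1", sep = "_")

aggregate_taxa(merged, bundle$taxonomy, "phylum") |>
  compartment_enrichment(soil_ids, seep_ids) |>
  filter(flag == "ok") |>
  arrange(desc(enrichment))
#> # A tibble: 6 × 6
#>   taxon                     source_mean target_mean enrichment lower_bound flag
#>   <chr>                           <dbl>       <dbl>      <dbl>       <dbl> <chr>
#> 1 Cand_Patescibacteria_like      0.0103     0.496       48.0            NA ok
#> 2 Phylum5                        0.0437     0.023        0.526          NA ok
#> 3 Phylum3                        0.452      0.235        0.519          NA ok
#> 4 Phylum2                        0.274      0.142        0.518          NA ok
#> 5 Phylum6                        0.201      0.0956       0.475          NA ok
#> 6 Phylum4                        0.0190     0.00878      0.463          NA ok
```

The planted rare-in-soil, strongly mobilized clade tops the enrichment
ranking by two orders of magnitude (1% of soil, ~50% of seepage), while
every other phylum is diluted — the qualitative signature of preferential
mobilization.

```r
gw <- bundle$bulk_water |> filter(grepl("^H[1-9][0-9]_", sample_id))
asm <- assembly_analysis(gw, bundle$tree, depth = 5000, n_reps = 199, seed = 1)
glance(asm)
#> # A tibble: 1 × 4
#>   n_pairs mean_beta_nti mean_rc_bray modal_process
#>     <int>         <dbl>        <dbl> <chr>
#> 1       6         0.550        0.935 dispersal_limitation

tidy(asm)[, c("sample_1", "sample_2", "beta_nti", "rc_bray", "process")]
#> # A tibble: 6 × 5
#>   sample_1 sample_2 beta_nti rc_bray process
#>   <chr>    <chr>       <dbl>   <dbl> <chr>
#> 1 H13_T1   H31_T1      0.674   1     dispersal_limitation
#> 2 H13_T1   H41_T1      1.53    1     dispersal_limitation
#> 3 H13_T1   H51_T1     -0.552   1     dispersal_limitation
#> 4 H31_T1   H41_T1      3.24    0.688 variable_selection
#> 5 H31_T1   H51_T1     -1.15    1     dispersal_limitation
#> 6 H41_T1   H51_T1     -0.448   0.920 undominated
```

Most pairs show |βNTI| < 2 (no dominant selection) with RC_bray saturated
at 1 — the dispersal-limitation signature the scenario planted.
`autoplot(asm)` draws the pairs on the βNTI-vs-RC_bray plane with the
decision thresholds. `infer_cooccurrence_network()`,
`spearman_profile()` and friends follow the same pattern; the methods
vignette (`vignettes/groundwater-community-assembly.Rmd`) documents every
model, default and design choice.

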