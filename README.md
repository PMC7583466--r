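# avipref

Street-tree availability and bird foraging-preference analysis.

Urban street trees are a censusable public resource, and wintering and
resident birds feed on them very unevenly. `avipref` is for ecologists who
have (or want to simulate) two field tables — a street-tree inventory
(species and DBH for every tree along walking routes) and a log of bird
feeding detections on those routes, across an income-stratified set of
residential communities — and want the complete analysis chain:

- **Availability** — per-species importance values
  `IV = (relative density + relative dominance) / 2`, with dominance the
  summed basal area `π (DBH/200)²` per species, standardized per km of route
  (`importance_values()`, `basal_area_from_dbh()`). No frequency term:
  routes are censuses, not plot samples.
- **Observation reduction** — raw detections to independent feeding units
  via flock collapsing (one unit per flock; one per species in mixed
  flocks), a 100-m same-species pseudo-replication rule, and a first-tree
  rule for multi-tree bouts (`reduce_observations()`).
- **Preference** — feeding proportions, the preference/aversion index
  `PI = use% − IV`, proportional use `100·use%/IV`, and χ² goodness-of-fit
  tests of use vs availability for common species (IV > 1.5%, n ≥ 30)
  (`preference_table()`, `use_availability_chisq()`).
- **Community comparison** — permutation ANOSIM (statistic `R ∈ [−1, 1]` on
  midranks, subset-permuted pairwise contrasts at Bonferroni α) on
  square-root Bray–Curtis dissimilarities, ANOVA / Kruskal–Wallis with
  Tukey or rank-based pairwise letters, Spearman rank correlation with a
  permutation p (`anosim()`, `bray_curtis()`, `pairwise_contrasts()`).
- **Density models** — negative-binomial GLMs (log link, θ by ML, handles
  non-integer per-km densities) of feeding-bird density against street-tree
  predictors, with quadratic terms, overdispersion diagnostics and ΔAIC
  ranking of the nine-model single-variable sets (`fit_model_set()`).
- **Synthetic studies** — a generator that emulates the income gradient (12
  routes per class; 54/81/113 trees·km⁻¹; 17/29/80 m²·km⁻¹; an 85-species
  log-series pool with natives enriched in high-income areas) and draws
  feeding events proportional to availability × preference multiplier, so
  planted preferences are recoverable end to end (`simulate_study()`).

## Worked example

```r
library(avipref)

st  <- simulate_study(seed = 2026)                 # routes, trees, detections
obs <- reduce_observations(st$detections, verbose = TRUE)
#> flock collapsing: 917 detections -> 943 units; 100-m rule dropped 55; 888 observations retained

iv <- importance_values(st$trees, st$routes)
pt <- preference_table(obs, iv, grouping = "migratory")
head(report_preference(pt), 5)
#>               species n_obs use_pct iv_pct preference_index proportional_use
#> 1 common crape myrtle    79    15.8  13.31             2.49              119
#> 2          carrotwood    21     4.2   2.62             1.58              161
#> 3   southern magnolia   126    25.2  24.01             1.19              105
#> 4      coast live oak    17     3.4   2.60             0.80              131
#> 5    Mexican fan palm    14     2.8   2.29             0.51              123

use_availability_chisq(obs, iv, grouping = "migratory")
#> Use vs availability chi-square goodness of fit (migratory)
#>   13 tree taxa with IV > 1.5 %; 400 feeding observations
#>   X-squared = 15.62, df = 12, p = 0.2094

counts <- route_species_counts(st$trees, st$routes)
anosim(bray_curtis(counts), st$routes$income_class, n_perm = 999, seed = 2026)
#> ANOSIM: 36 sites in 3 groups
#>   R = 0.566, p = 0.001 (999 permutations)
#>   pairwise contrasts (Bonferroni alpha = 0.0167):
#>            pair     R     p significant
#>     high vs low 0.864 0.001        TRUE
#>  high vs medium 0.541 0.001        TRUE
#>   low vs medium 0.410 0.001        TRUE
```

Read the tables: `use_pct` is the share of the migratory birds' feeding
observations on each tree species, `iv_pct` its availability; a
`preference_index` of 2.49 means crape myrtle drew 2.49 percentage points
more feeding than its availability, and `proportional_use = 119` means 119%
of availability. The ANOSIM `R = 0.566` with `p = 0.001` says street-tree
communities differ strongly across the income gradient (this simulated
study's gradient is deliberately strong); every pairwise contrast clears the
Bonferroni-adjusted α of 0.0167. `run_pipeline()` chains all of the above,
adds the Kruskal–Wallis route-density comparisons and the NB model sets,
and writes a manifest for reproducibility.

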