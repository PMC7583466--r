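---
title: "Street-tree availability and bird foraging preference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Street-tree availability and bird foraging preference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avipref)
```

## The scientific problem

Street trees are a public, censusable component of the urban forest, and
foraging birds use them unevenly: some species are fed on far more than their
abundance would predict, others are avoided. `avipref` implements the full
chain of analysis needed to quantify that pattern from two field data sets —
a street-tree inventory (every tree on a set of walking routes, with species
and diameter at breast height) and a log of bird feeding detections on those
routes — collected across residential communities stratified by median
household income (a "luxury effect" gradient: wealthier neighbourhoods carry
denser, larger street trees).

## Availability: species importance values

A tree species' availability as foraging substrate is summarized by its
importance value,

$$IV_s = \tfrac{1}{2}\left(100\frac{n_s}{\sum_t n_t} +
100\frac{BA_s}{\sum_t BA_t}\right),$$

the average of its relative density and relative dominance, where the
dominance of species $s$ is its summed basal area
$BA_s = \sum_i \pi (d_i/200)^2$ in m² from DBH $d_i$ in cm. The classical
third term of importance values, frequency, is omitted by construction:
walking routes are censuses of a right-of-way, not plotless samples of forest
stands, so a frequency metric is undefined. `importance_values()` computes
relative values over the pooled all-route inventory by default; a
`per_route = TRUE` mode exists because per-km figures can also be read as
means of route-level values, and the two conventions differ — pooled is the
default and is what every downstream analysis uses. IVs sum to 100 over the
species set by construction, which the test suite asserts to $10^{-9}$ on
every generated data set. Family-level labels ("Fraxinus spp.") and "unknown
nonnative" are ordinary species labels here; origin is resolved from a
configured native-species list, with unlisted labels defaulting to nonnative.

## From raw detections to observation units

Raw detections overcount: flocks move between trees as a unit, the same bird
can be re-sighted metres later, and one bird may feed in several trees during
an observation. `reduce_observations()` applies three rules, in order:

1. **Flock collapsing** — a single-species flock is one unit; a mixed-species
   flock is one unit per member species (`collapse_flocks()`).
2. **100-m rule** — a detection of a species within 100 m of where the
   previous *retained* observation of that species ended, on the same route
   and visit, is dropped, unless the birds were visibly distinct male/female
   (`dedupe_observations()`). The rule is applied per route × visit
   independently: visits are weeks apart and treated as independent. The
   ambiguous reading — comparing to the previous *raw* rather than retained
   detection — would only drop more; we implement the retained-detection
   comparison and document the choice here.
3. **First-tree rule** — a bout across several trees contributes the first
   tree only (`first_tree_rule()`).

The reduction is idempotent, never invents units, and its per-rule drop
counts are reported (`verbose = TRUE`) because they are part of the analysis
surface. Whether flock collapsing costs effect size is checked with
`flock_sensitivity()`, a Spearman rank correlation between reduced unit
counts and full individual tallies per route.

## Preference, aversion, and use vs availability

For a bird grouping (a species, the migratory pool, the year-round pool, or
all birds), `feeding_proportions()` gives each tree species' share of the
grouping's feeding observations (`use_pct`). Two descriptive statistics and
one test follow:

- **Preference index** $PI = use\% - IV$: positive is preference, negative
  aversion. Over the complete species set $\sum PI = 0$, and a species with
  zero use has $PI = -IV$ exactly — which is also why printed preference
  tables let one recover IVs from their constant negative columns.
- **Proportional use** $= 100 \cdot use\% / IV = 100(IV + PI)/IV$: use as a
  percentage of availability.
- **χ² goodness of fit** (`use_availability_chisq()`): observed feeding
  counts against expectations proportional to IV, restricted to common
  species (IV strictly > 1.5%) and groupings with ≥ 30 observations.

Two conventions needed a decision. The preference index uses raw IVs over
the full inventory (not renormalized to the common-species subset): this is
the only convention under which the zero-use identity and the proportional-
use arithmetic are mutually consistent. The χ² test, by contrast,
renormalizes IVs over the included species so expected counts sum to the
observed total (`renormalize = TRUE`, with the non-renormalized variant
exposed). Groupings that fail the ≥ 30-observation floor are reported as
excluded rather than raising an error, so a batch over many groupings
degrades gracefully. These statistics are descriptive of preference, not
resource-selection estimates — availabilities are unequal by design.

## Community and group comparisons

Route-level community structure is compared with an analysis of
similarities (`anosim()`) on Bray–Curtis dissimilarities of square-root
transformed counts (`bray_curtis()`; two all-zero rows are defined to have
dissimilarity 0). The R statistic uses midranks throughout, and the
permutation p-value is the positively biased estimator
$(1 + \#\{R^* \ge R\})/(n_{perm} + 1)$, which can never report $p = 0$; with
the default 999 permutations the smallest attainable p is 0.001. Pairwise
group contrasts re-permute within each pair's subset of routes (rather than
slicing a full-design permutation), judged at a Bonferroni-adjusted
$\alpha = 0.05/\text{pairs}$. R is a rank statistic, so it is invariant to
monotone transforms of the dissimilarities; the suite asserts this
numerically, matches the statistic against an independent implementation,
and checks the Monte-Carlo p against exhaustive enumeration on small
designs.

Scalar route variables (densities, basal areas, richness) are compared
across income classes with a one-way ANOVA or Kruskal–Wallis test, followed
by Tukey HSD or — in place of the "relative contrast effects" procedure,
whose full machinery is out of scope here — Bonferroni-adjusted pairwise
Wilcoxon rank-sum tests, with a compact letter display (groups sharing a
letter do not differ). `spearman_rho()` computes the rank correlation with a
seeded permutation p (10⁴ permutations by default).

## Feeding-bird density models

`fit_model_set()` fits, per response (migratory, year-round, total per-km
feeding density), one negative-binomial GLM per street-tree predictor plus
the intercept-only reference — the nine-model, single-variable design —
and ranks them by AIC (ΔAIC = 0 marks the best-supported model).
Fitting delegates to `MASS::glm.nb` (log link, NB2 variance
$\mu + \mu^2/\theta$, θ by maximum likelihood). Three details matter:

- The response is a **non-integer per-km density**. The NB log-likelihood is
  evaluated through its gamma-function form, which extends continuously to
  non-integer values; this is the default, with `integer_mode = TRUE`
  rounding first for strict-count semantics.
- Coefficients are reported **exponentiated**; the intercept-only model's
  exponentiated intercept equals the response mean exactly (a property the
  acceptance tests assert to $10^{-6}$ relative).
- Quadratic terms use the raw predictor, not a centred one; hump-shaped
  relationships show up as exponentiated quadratic coefficients below 1.
  Overdispersion is diagnosed by the Pearson χ² statistic and the residual
  deviance / residual df ratio (`overdispersion_check()`, verdict threshold
  1.5), the workflow being Poisson first, NB when the Poisson fit is
  overdispersed. Significance flags come from Wald z-tests.

## What the synthetic generator emulates — and what it does not

`simulate_study()` generates data with the statistical structure the
analysis assumes, so every stage is testable without field data. Its
defaults are the study conditions: 36 routes, 12 per income class, lengths
$\mathcal N(2.49, 0.1^2)$ km; class-mean tree densities 54 / 81 / 113 per km
and basal areas 17 / 29 / 80 m² per km; an 85-species pool with a log-series
abundance distribution, 5 native species of which two are common, natives
enriched from ~1% of trees in low-income to ~7% in high-income routes; and a
detection rate of 0.031 per tree per visit over 4 visits, which yields on
the order of 900 reduced observations — the scale of the original surveys.
DBH is lognormal per species (within-species log-sd 0.45, between-species
0.15), with the class-level mean squared diameter solved so expected basal
area hits the class target.

The feeding mechanism is the part the preference tests lean on: each
detection's tree is drawn with probability proportional to *availability ×
preference multiplier*, where a tree's availability is half its count share
plus half its basal-area share — so a species' total draw weight is
proportional to $IV_s \times w_s$ exactly. With all $w = 1$ the pipeline
must recover no preference (the suite requires $|PI| < 2$ points at ~5,000
observations); with $w = 3$ planted on one species, recovered proportional
use is pulled below 300% only by that species' own inflated share in the
denominator, a shrinkage of $1/(1 + 2 IV_s/100)$ that the recovery band
accounts for. A per-route gamma multiplier (CV 0.3) on detection intensity
adds the between-route overdispersion that motivates the NB models; because
it is independent of tree species, it perturbs preference recovery without
biasing it. Flocks (including mixed ones), male/female-distinct detections,
multi-tree bouts and tree-anchored positions are generated so every
reduction rule is exercised.

What the generator does **not** emulate: spatial autocorrelation of species
along a route (positions are uniform), yard vegetation and landscape
context, phenology (no substrate seasonality), observer effects, and the
very flat top of the real street-tree abundance distribution (a log-series
is steeper; any heavy-tailed SAD satisfies the tested moments). Passing
tests therefore certify the statistical machinery and the recovery
properties under these idealized conditions, not the field realism of any
particular parameter.

## Numerical choices and problem sizes

Midranks everywhere ranks are taken; permutation p-values always use the
$(1+c)/(1+n)$ estimator; percentages are carried at full precision and
rounded only in the report layer (`report_preference()`: two decimals, with
proportional use displayed as integer percent); income terciles classify
with closed boundaries (≤ low-max is low, ≥ high-min is high). Degenerate
inputs fail loudly: non-positive DBH or route lengths, empty inventories,
constant dissimilarity matrices, zero within-group variance, all-tied
Kruskal–Wallis data, and non-positive IVs in preference arithmetic are all
errors, while an under-sampled χ² grouping is a reported exclusion.

Test problem sizes are chosen for tight statistical bounds at desk scale:
NB calibration uses 100 replicates of n = 500; preference recovery uses 50
full synthetic studies (~7,400 trees, ~900 observations each); generator
calibration averages 20 seeds; ANOSIM null behaviour uses 200 replicates
and its p-value oracle an exhaustively enumerable 6-route design.

## Known limitations

The pairwise nonparametric contrasts are Bonferroni-adjusted Wilcoxon tests,
not the relative-contrast-effects procedure, and can be conservative. The
ANOSIM pairwise contrasts re-permute within subsets, one of two defensible
designs. Preference indices inherit all caveats of use/availability ratios
for rare species (an IV near zero makes proportional use explode), which is
exactly why the χ² analysis gates on IV > 1.5% and n ≥ 30. The NB continuous
extension treats densities as if counts, which is the field's standard
practice but not a formally derived likelihood for rates.
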