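---
title: "Kappa and colocation quotients for spatial rating reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kappa and colocation quotients for spatial rating reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clqkappa)
```

## The model

Participants of a geocoded survey rate an attribute of their close
outdoor environment on a categorical scale with $c$ categories,
possibly including indefinite ("cannot say") and missing answers as
categories of their own. Two people living close together rate largely
the same environment, so their agreement is informative about the
reliability of the rating instrument. The unit of analysis is the
*matched set*: one index rater together with their first-order nearest
neighbor(s) within a maximum radius (default 500 m). When $m_i$
neighbors are tied at the minimum distance, each enters with weight
$1/m_i$; after weighting every set contributes as though it contained
two raters. Raters with no neighbor inside the radius are excluded and
counted.

From $n$ matched sets the weighted index-by-neighbor contingency table
is
$$o_{ab} = \frac{1}{n} \sum_{i=1}^n \frac{1}{m_i}\, x_i(a, b),$$
where $x_i(a,b)$ counts neighbors rated $b$ in set $i$ when the index
rating is $a$. The index margins $p_a$ are the relative counts of
index ratings over the analyzed sets; chance expectations use them for
both sides, under the assumption that the neighbors share the index
raters' overall rating distribution (the weighted neighbor margins are
reported so this can be checked; the discrepancy is typically a few
tenths of a percent).

Two association measures are computed for every ordered pair $(a, b)$:

* the **colocation quotient**
  $\mathrm{CLQ}(a,b) = o_{ab} / (p_a p_b)$, with a
  sampling-with-replacement convention (the index rating is included in
  the chance expectation, so there is no $(N-1)$ correction); and
* the **kappa statistic** on the $\{a,\neg a\}\times\{b,\neg b\}$
  dichotomization,
  $\kappa(a,b) = (P_O - P_E)/(1 - P_E)$ with
  $P_E = p_a p_b + (1-p_a)(1-p_b)$, where $P_O$ sums the two agreement
  cells of the dichotomized table. For $a = b$ this is the
  category-specific kappa, and it equals the overall kappa of the
  collapsed 2x2 table (an identity the test suite asserts to
  $10^{-12}$ on random tables).

CLQ is bounded above by a margin-dependent maximum. Conditioning on the
total share $p_a + p_b$ and assuming equal occurrence of the two
ratings, the maximal colocation is $(p_a+p_b)/2$, while the chance
expectation stays $p_a p_b$, giving
$$\mathrm{CLQ}_{\max} = \frac{p_a + p_b}{2\,p_a p_b},$$
which reduces to $1/p_a$ for a single category. Normalizing,
$$\kappa \approx \frac{\mathrm{CLQ} - 1}{\mathrm{CLQ}_{\max} - 1}
  = \frac{2 p_a p_b\,(\mathrm{CLQ} - 1)}{p_a + p_b - 2 p_a p_b},$$
with equality when index and neighbor margins coincide for the pair
(asserted to $10^{-9}$ on 1000 random equal-margin tables). This makes
the two measures interchangeable: CLQ has the direct reading "how many
times more likely than chance", kappa expresses the same association as
a share of the maximum attainable excess agreement, which is the
appropriate scale for comparing or combining categories with different
prevalences.

## Inference under the no-agreement null

The classical two-rater null SE of kappa (Fleiss-Cohen-Everitt),
$$SE_0 = \sqrt{\frac{P_E + P_E^2 - \sum_i r_i s_i (r_i + s_i)}
  {n (1 - P_E)^2}},$$
treats the $n$ sets as independent rater pairs. A nearest-neighbor
design violates this in a specific, known way: many raters are each
other's nearest neighbor, so the same two ratings enter twice (for a
same-category statistic the two agreement indicators are *identical*),
and one rater can serve as the neighbor of several index raters. In
simulation the plain formula under-estimates the same-category null SD
by 15-20% in survey-like geometries, which inflates the type-I error of
the $|\kappa|/SE$ test from 5% to roughly 13%.

`null_se()` therefore computes the permutation-null variance from the
Hoeffding decomposition of the dichotomized agreement indicator
$A = [x_i{\in}a][x_j{\in}b] + [x_i{\notin}a][x_j{\notin}b]$. Under
random relabeling with the margins estimated from the index raters, the
index-linear component cancels against the margin estimate; what
remains is

* the neighbor-linear function of each rater's rating, entering with
  that rater's neighbor-service weight minus index-service weight — a
  weighted linear statistic whose permutation variance is exact; and
* the interaction component, contributing through the squared tie
  weights plus a covariance term for mutual (reversed) pairs.

All ingredients are margin moments and four weighted counts of the pair
graph that `nearest_neighbor_sets()` stores with the matched sets. For
a design of independent disjoint pairs the expression reduces to the
classical formula, which is also what `null_se()` falls back to when a
table is supplied as a bare matrix via `as_wct()` (no geometry known).
Against a 2000-draw permutation null the computed SE agrees within
about 2% across radii, sample sizes and category prevalences (the
acceptance suite enforces 15%), and the $|\kappa|/SE_0$ test holds its
5% size within binomial bounds over 200 null replicates. The
permutation null itself (`permutation_null()`) remains available as the
assumption-free reference; it reassigns ratings across all rater
locations, preserving the margins and destroying the spatial
arrangement.

P-values are two-sided normal, starred `*` for $0.01 \le p < 0.05$,
`**` for $p < 0.01$, `***` for $p < 0.001$.

## Collapsing categories

Whether two scale points can be merged without losing reliability is
decided by three criteria: (i) the pair clusters spatially
(CLQ > 1 and kappa > 0); (ii) the cross-category CLQ is of the same
magnitude as the lower of the two same-category CLQs; (iii) the merged
category's same-category kappa exceeds both originals. Criterion (ii)
is qualitative; it is operationalized as
$\mathrm{CLQ}(a,b) \ge (1-\tau)\min(\mathrm{CLQ}(a,a),\mathrm{CLQ}(b,b))$
with $\tau = 0.15$ by default. That value reproduces the customary
judgement calls — a cross-CLQ of 1.3 against same-category 1.7/1.3
passes, 1.2 against 1.4/1.5 sits at the border — and is exposed as a
parameter because no sharp threshold is inherent in the criterion.
Kappa, not CLQ, judges criterion (iii): CLQ maxima change when margins
merge, so CLQ values before and after a collapse are not on a common
scale, while kappa is always a share of its maximum.

Only user-proposed groupings (or all within-group pairs of one
grouping) are evaluated; there is no automated search over partitions,
and validity of a merge — whether the two ratings measure the same
construct — is outside what colocation can show.

## The synthetic generator

`simulate_ratings()` emulates the study conditions the package is
designed for: rater locations uniform on a square domain; a latent
environment laid out as a square grid of patches, each drawing one
latent level; ratings produced by pushing the patch level through a
row-stochastic misclassification matrix; then independent overrides to
the indefinite and missing codes. Defaults give a rater density with a
median nearest-neighbor distance of ~35 m, informative margins near
14/34/38/13% before overrides, 7% indefinite and 4.2% missing answers,
and adjacent-level reporting noise (`p_stay = 0.55`) producing
same-category kappas in the 10-20% range — the regime reported for
perceived-greenness surveys.

The square patch grid is the simplest spatially coherent field: patch
side controls how often matched neighbors share a latent level,
standing in for overlapping neighborhood environments. What it does
*not* reproduce: realistic population density (urban clustering,
roads), distance-decaying rather than sharp environment boundaries,
spatially clustered non-response, and covariate-driven perception
differences between neighbors. Passing calibration tests on this
generator therefore show that the statistics behave correctly when
their sampling assumptions hold approximately — not that any given
survey meets those assumptions.

Parameter recovery is asserted in the acceptance suite: with identity
misclassification and patches much larger than the typical
nearest-neighbor spacing, same-category kappa exceeds 0.9 (it
approximates the probability that a matched pair shares a patch); with
adjacent-level noise, neighboring scale points cluster
(CLQ > 1) and distant ones separate (CLQ < 1); with
location-independent ratings all statistics sit at their chance levels.

## Numerical choices and edge cases

* **Tie detection** uses an absolute tolerance of $10^{-9}$ m —
  survey geocoding is many orders of magnitude coarser, so this only
  guards against floating-point jitter in genuinely equal distances.
  Distance 0 (same building) is a legal neighbor; a rater is never its
  own neighbor.
* **Metric**: planar Euclidean on projected meter coordinates by
  default; Haversine great-circle for lon/lat as an option. The
  Euclidean search is compiled and exact (no approximate spatial
  index); the suite checks it against an O(n²) scan on 100 random
  configurations.
* **Undefined statistics** (zero margins, degenerate $P_E = 1$) are
  reported as `NA` with a typed warning and a `defined` flag — never
  as 0 or infinity.
* **Margins** are computed over the analyzed sets only; excluded
  raters contribute neither to $p_a$ nor to the table (they do remain
  in the permutation pool, and the SE accounts for their zero service
  weights).
* **Display rounding** mirrors the conventional presentation — CLQ to
  two significant figures, kappa in percent with one decimal below 10%
  — while all stored and exported values keep full precision. A
  near-symmetric table is rendered upper-triangle only, with the
  maximal CLQ asymmetry reported as a diagnostic.
* **Problem sizes in the test suite** were chosen to make Monte-Carlo
  bounds tight at interactive runtimes: 200 replicates of 5000 raters
  for null calibration, 2000 permutations at ~700 sets for the SE
  oracle, generators of 3000-6000 raters for parameter recovery.

## Known limitations

Inference is global: one statistic per category pair for the whole
study region, with equal weight per matched set regardless of
neighbor distance. Local (geographically weighted) colocation, ordinal
weighted kappa, higher-order neighbors and network distances are out of
scope. The CLQ-kappa normalization is exact only under equal index and
neighbor margins; with strongly drifting margins the exact
`kappa_exact()` should be preferred (both are always reported).
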