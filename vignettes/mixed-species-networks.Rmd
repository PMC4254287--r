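---
title: "Randomization tests and simulations for mixed-species grouping networks"
author: "mixnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomization tests and simulations for mixed-species grouping networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixnet)
```

## The data model

The sampling unit is a *cluster*: an independent sighting of one or more
mammal species whose individuals were within 50 m of one another (the 50 m
co-membership rule and the 500 m scan radius are data-collection
conventions; the package takes cluster membership as given and never
re-derives it from coordinates). A cluster containing two or more species is
a *mixed-species group*. Records are stored in long format, one row per
species occurrence within a cluster, carrying the cluster's ecosystem,
season and habitat plus the species' conspecific group size (the number of
individuals of that species, distinct from the cluster size, which counts
species).

A record set is summarised as a binary occurrence matrix with clusters as
rows and species as columns. Its margins are the two quantities every
analysis conditions on: row sums are cluster sizes (species per cluster) and
column sums are per-species sighting counts. Because detection probabilities
differ strongly between species, absolute abundances are unknowable from
sighting data alone; all tests below therefore condition on these margins
instead of modelling abundance.

Species metadata live in a catalog with feeding guild and effective strip
width (ESW, metres), a distance-sampling summary of detectability. The
shipped catalog has 26 entries (pooling the three sympatric jackal species
into one). Network-level analyses are restricted to highly detectable
species via `filter_by_detectability()`; the default threshold of 230 m is
*inclusive*, because one retained species sits exactly at 230 m, and returns
10 species. Habitat takes one of six values (grassland, open bushland,
closed bushland, woodland, riverine, shrubland); a cluster has exactly one
habitat — records spanning a boundary must be assigned to one label before
import, since the data model (and the habitat-stratified null) needs a
single stratum per cluster.

## The fixed-margin null and the Besag–Clifford test

The null hypothesis of "no association" is: given the observed number of
clusters, their sizes, and each species' number of occurrences, all
arrangements of species into clusters are equally likely — i.e. the uniform
distribution over binary matrices with the observed margins. Sampling this
distribution uses the standard reversible chain on fixed-margin binary
matrices: propose a uniformly random row pair and column pair; if the 2×2
submatrix alternates 0/1, flip it, otherwise stay. The proposal kernel is
symmetric, so the chain's stationary law is uniform on the connected
fixed-margin class. With habitat stratification, flips are restricted to
same-habitat row pairs, which conditions the null additionally on each
habitat's cluster composition.

Because chain convergence is hard to certify, p-values use the
Besag–Clifford serial scheme, which is *exactly* valid at any run length:
the observed matrix is placed at a uniformly random position $U \in \{0,
\dots, m\}$ of a stationary path of $m+1$ states. Exploiting reversibility
and kernel symmetry, the backward half of the path is realized as an
ordinary forward run, so the implementation runs the chain twice from the
observed matrix (recording $U$ and $m-U$ states respectively) and reports

$$ p_\text{upper} = \frac{1 + \#\{T_i \ge T_\text{obs}\}}{m + 1}, $$

with the mirror image for the lower tail. Ties count as exceedances in both
tails and the add-one correction means a p-value can never be zero; the
resolution is $1/(m+1)$. The construction matters: a superficially similar
variant (run $U$ steps away from the data, then record one fresh forward
run) is only pairwise exchangeable with the data and proved measurably
anticonservative for slow-mixing statistics during development, so the
path-embedded version above is the one implemented.

`thin` (proposals between recorded states, default one expected sweep = the
number of matrix cells) trades runtime against autocorrelation of the
recorded statistics; validity does not depend on it, only the power of the
test does. Reported run lengths in the millions of raw proposals correspond
to modest `m` at default thinning; desk-scale analyses in the tests use `m`
of a few hundred (resolution 1/200 or better), while `m = 10^4` is used
when comparing against exact enumeration.

## The three association statistics

All three statistics are functions of the pairwise co-occurrence counts
$w_{ij}$, the number of clusters containing both species:

* **Global association (ASSS)**: $\sum_{i<j} w_{ij}^2$, large when species
  concentrate their co-occurrences on specific partners; the upper tail is
  the reported direction.
* **Dyadic association**: $w_{ij}$ for one named pair. Raw counts are a
  valid statistic precisely because the randomization conditions on each
  species' sighting count — a rare pair can be significant with few
  co-occurrences while an abundant pair with many is not.
* **Node strength**: $s_i = \sum_{j \ne i} w_{ij}$, the total edge weight
  incident to a species. Both tails are informative: the lower tail flags
  species that avoid mixed groups, the upper tail heterospecifically
  gregarious ones. Both are always reported; the caller decides the alpha
  split (a two-sided reading at 5% treats 0.025 per tail).

No multiple-testing correction is applied by default (per-test p-values are
reported raw); `association_table(adjust = "BH")` offers
Benjamini–Hochberg when many dyads are scanned.

## Group-size permutation tests

Whether a species' conspecific group sizes differ between single- and
mixed-species clusters (or between partner-present and partner-absent
occurrences) is tested by permuting that species' observed group-size list
over the fixed context labels, keeping the species' total count of observed
individuals constant. The statistic is the difference of context medians,
two-sided via its absolute value; medians of even-length lists use the
midpoint convention. When the number of distinct label assignments is small
(up to 20,000 combinations) the test enumerates all of them exactly;
otherwise it Monte-Carlo samples with the add-one correction. A context
with zero occurrences makes the comparison meaningless, so the result is
explicitly flagged untestable rather than given a p-value. The design is
deliberately asymmetric: testing species A against partner B uses A's group
sizes only.

## The species network and betweenness

Species are nodes; an edge of weight $w_{ij}$ joins every co-occurring
pair. Weighted networks are essential here because any edge is possible and
the information is in the weights; the analysis default keeps all positive
weights (`min_weight = 1`), while a display threshold of 2 matches the
figure convention of the study system. Betweenness uses shortest paths with
edge length $1/w_{ij}$: frequently co-occurring species are "close", so the
score measures how often a species sits on the most-contact-heavy routes
between others — a proxy for its role in cross-species information or
pathogen flow. The length transform is a documented choice (the reciprocal
is the standard conversion of an affinity weight into a distance and
matches the convention that short drawn edges mean many co-occurrences); a
`binary = TRUE` fallback ignores weights entirely for sensitivity checks.
Scores are unnormalized; comparisons across ecosystems, seasons and
simulation replicates use descending ranks (ties averaged), which are
robust to network size and total sampling effort.

## The cluster simulator

The simulator asks whether a species' network position is explained by its
abundance alone or requires its preferences. It has three steps:

1. Draw $N$ species occurrences i.i.d. from the relative sighting
   frequencies.
2. Form clusters: repeatedly draw a target size from a geometric
   distribution $P(n) = (1-p)^{n-1} p$ (estimated by $\hat p = 1/\bar n$
   from observed cluster sizes, truncated at the species count by
   resampling) and fill the cluster by drawing occurrences without
   replacement from the pool, never repeating a species within a cluster,
   until all $N$ occurrences are assigned.
3. Optionally introduce preferences: $k$ random swap proposals, each
   exchanging one species occurrence between two clusters, rejected if the
   swap would duplicate a species within a cluster or strictly increase the
   sum of squared differences between simulated and observed *relative*
   association strengths ($w_{ij}$ divided by the total co-occurrence
   count). Swaps conserve cluster sizes and per-species totals, and the
   difference score is non-increasing by construction. The default
   `k = 10000` follows the study's setting, where any value above a
   thousand behaved similarly.

Step 2 needs a tail policy the three-step description leaves open: when the
remaining pool cannot supply the drawn size without duplicating a species,
the cluster closes at the largest feasible size and the leftovers seed
further clusters, preserving "every occurrence is assigned" with minimal
distortion of the size distribution. Internally a swap is a 2×2
checkerboard flip on the occurrence matrix (which is exactly why it
conserves both margins), with the score delta computed incrementally over
the affected pairs — the total co-occurrence count is invariant because
cluster sizes are.

Repeating the simulation (default 1000 replicates; the test suite and the
reproduction script use 200) and computing betweenness ranks per replicate
yields, per species, a mean rank with 5% and 95% percentiles
(inverse-ECDF percentiles, so two replicates give min and max). Abundance-
only bands (steps 1–2) show what relative abundance alone produces;
preference bands (steps 1–3) reproduce the observed association structure
and show how robust an observed rank is to sampling noise. A species whose
observed rank falls inside the abundance-only band needs no preference
story; one outside it does.

## The synthetic ground-truth generator

Validation needs data with known structure. `ground_truth()` describes a
community: relative frequencies, planted pairwise preferences (odds
multipliers $\varphi \ge 1$, with $\varphi = 1$ exactly recovering the
null), planted solitary species (all their pairwise odds divided by a
strength factor), an overdispersed conspecific group-size model (1-shifted
negative binomial, with partner-conditional mean multipliers to plant
group-size effects), and a habitat mixture. `generate_community()` draws
clusters with the simulator's pool machinery but injects preferences at
fill time — a candidate species enters a cluster with probability
proportional to its remaining occurrences times the product of its
$\varphi$'s with the species already present. This generator-side mechanism
is deliberately different from the analysis-side swap step, so the
generator cannot trivially agree with the analysis it validates. Because
the caller fixes the number of clusters, the community generator uses a
sizes-first variant of step 2: draw all target sizes, build an exactly
matching occurrence pool, fill as usual.

Defaults are fixed at values emulating the study system and are not tuned
per test: the 10 high-detectability species; strongly skewed frequencies
(geometric series, ratio 0.75); $p = 0.8$ (observed mean cluster sizes of
1.22–1.35 across ecosystems and seasons imply $p$ between roughly 0.74 and
0.82); group-size mean 4 with dispersion 1.2 (heavy-tailed herd sizes);
uniform habitat mixture. What the generator does *not* emulate: spatial
structure and movement, observer-detection error beyond the ESW filter
concept, seasonal migration, and any dependence between habitat and species
composition. Passing tests therefore demonstrate correctness of the
machinery under these idealized conditions, not field realism.

## Numerical choices and scales

* Random integers in the compiled kernels come from R's RNG, so a single
  `set.seed()` (or the `seed` arguments) reproduces every result bit for
  bit; simulation replicates consume one RNG stream seeded once.
* Swap acceptance uses a `1e-12` tolerance so that exact ties are accepted
  (a tie cannot increase the score) and floating-point drift cannot
  accumulate: the maintained score is clamped at zero.
* Exhaustive enumeration in the group-size tests caps at 20,000
  combinations; beyond that, add-one Monte Carlo.
* Test-suite scales: calibration uses 200 null communities of 300 clusters;
  power uses 100 communities of 2000 clusters with $\varphi = 8$;
  distributional checks use $10^5$ occurrences; chain conservation uses
  $10^5$ proposals; rank bands use 200 replicates per mode. These sizes
  keep the default suite comfortably reproducible on a single core.

## Known limitations

* **The generative null is not exactly the randomization null.** Step 2
  fills clusters proportionally to remaining abundance, so abundant species
  pair somewhat more often than under the uniform fixed-margin ensemble,
  which distributes 1s combinatorially and carries an entropic repulsion
  between high-occupancy columns. The effect concentrates on abundant
  pairs: at the suite's calibration scale the dyad test's empirical size
  against abundance-only generator data is about 0.09 for the two most
  abundant species but 0.02 (conservative) for a mid-abundance pair, the
  node-strength test sits near 0.06–0.08, and the global ASSS statistic —
  which sums the excess over all pairs — reaches 0.11–0.17 at nominal
  0.05. The tests themselves are exactly valid for their stated
  fixed-margin null (empirical size ~0.05 on chain-sampled data with
  identical margins); the inflation is a property of the generative model,
  so rejections on data believed to follow the abundance-only generator —
  especially global-test rejections, or dyad rejections for the very most
  abundant pairs — should be read with this in mind.
* Betweenness on small, dense networks has many near-ties; ranks (the
  comparison currency) absorb most but not all of this instability.
* The chain's connectivity over the fixed-margin class is a classical
  property of checkerboard flips; the uniformity diagnostic in the test
  suite verifies it on small enumerable classes only.
* A planted "hub" is only recoverable as the top-betweenness species if the
  plant is strong enough to dominate abundance-driven edges; preferences
  planted on rare species correctly do *not* produce observed hubs, and the
  simulator then correctly does not rank them first.
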