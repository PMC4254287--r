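# mixnet

Randomization tests and simulations for mixed-species grouping networks.

Large African savannah mammals are often sighted in clusters containing
several species. Are those mixed-species groups the product of social
preferences, or just of species abundances? `mixnet` implements the
analysis pipeline for answering that question from sighting records of
single- and mixed-species clusters, for ecologists working with
presence-style survey data:

* **Margin-preserving randomization tests.** The null of "no association"
  conditions on everything detectability contaminates: the number of
  clusters, their sizes (species per cluster), and each species' sighting
  count. The null ensemble is the uniform distribution over binary
  occurrence matrices with those margins, sampled with a checkerboard-swap
  Markov chain (optionally stratified by habitat), and p-values use the
  Besag–Clifford serial scheme, which is exactly valid without any chain
  convergence requirement: `p_upper = (1 + #{T_i >= T_obs}) / (m + 1)`.
  Three test statistics: the global association score
  `ASSS = sum_{i<j} w_ij^2`, the dyadic co-occurrence count `w_ij`, and the
  node strength `s_i = sum_j w_ij` (lower tail = avoidance of mixed groups,
  upper tail = heterospecific gregariousness), where `w_ij` counts clusters
  containing both species i and j.
* **Group-size permutation tests.** Within one species, conspecific group
  sizes are permuted over fixed context labels (single- vs mixed-species
  cluster, or partner present vs absent), statistic = difference of context
  medians, exact enumeration when feasible.
* **Weighted co-occurrence networks.** Species as nodes, `w_ij` as edge
  weights, betweenness with edge length `1/w_ij`, and descending
  average-tie ranks as the comparison currency.
* **A three-step cluster simulator** separating abundance from preference:
  (1) draw N occurrences from the relative sighting frequencies, (2) pack
  them into clusters whose sizes follow a geometric law
  `P(n) = (1-p)^(n-1) p` with `p` estimated as the inverse mean cluster
  size, (3) optionally run k = 10000 swap proposals that pull the simulated
  relative association strengths toward the observed ones (a proposal that
  would increase the squared distance is rejected). Replicate betweenness
  ranks give per-species expectation bands under "abundance only" and
  "abundance + preferences".
* **A synthetic ground-truth generator** (known planted dyads, solitaries,
  group-size effects) so every stage is testable without field data.

## Worked example

A synthetic community of the ten high-detectability catalog species, with a
planted wildebeest–zebra preference (odds multiplier 8) and giraffe planted
as a mixed-group avoider:

```r
library(mixnet)

truth <- ground_truth(planted_dyads = data.frame(a = "Wb", b = "Ze", phi = 8),
                      planted_solitaries = "Gi", seed = 42)
records <- generate_community(truth, 1500)
mat <- build_occurrence_matrix(records)

test_global_association(mat, m = 999, seed = 1)
#> global_association test (ASSS): stat = 12781, p_upper = 0.145, p_lower = 0.856 (m = 999)
test_dyad(mat, c("Wb", "Ze"), m = 999, seed = 2)
#> dyad test (Wb-Ze): stat = 14, p_upper = 0.001, p_lower = 1 (m = 999)
test_node_strength(mat, "Gi", m = 999, seed = 3)
#> node_strength test (Gi): stat = 103, p_upper = 1, p_lower = 0.001 (m = 999)
```

The planted dyad is recovered: 14 wildebeest–zebra co-occurrences is far
more than the fixed-margin null produces (`p_upper = 0.001`, the smallest
value possible at m = 999). The planted solitary is recovered on the lower
tail of node strength (`p_lower = 0.001`): giraffes sit in mixed groups far
less than their 103-edge-weight sighting frequency predicts. The global
score is dominated by abundance-driven pairs and is not significant here —
one planted dyad among 45 pairs is a dyad-level, not community-level,
signal.

Are observed network positions explained by abundance alone? Compare each
species' observed betweenness rank with its abundance-only simulation band:

```r
counts <- co_occurrence_counts(mat)
net <- network_from_counts(counts)
obs_rank <- betweenness_ranks(betweenness_scores(net))
cfg <- simulation_config(colSums(unclass(mat)) / sum(mat), sum(mat),
                         p = estimate_geometric_p(rowSums(unclass(mat))),
                         n_reps = 200, seed = 7)
rp <- simulate_betweenness_ranks(cfg)
data.frame(species = rp$species, observed = obs_rank[rp$species],
           expected = round(rp$mean_rank, 1), lo = rp$p5, hi = rp$p95)
#>  species observed expected lo  hi
#>       Gi      6.5      3.1  1 6.5
#>       Hi      1.0      1.1  1 2.0
#>       Ha      6.5      6.6  6 7.0
#>       Wb      2.0      6.5  6 7.0
#>       ...
```

Hippo's top rank is exactly what its abundance predicts (observed 1.0,
band 1–2). Wildebeest's observed rank of 2.0 lies far outside its
abundance-only band (6–7): its central position can only come from its
planted association with zebra — the preference-detection logic of the
simulator in one table.

The same operations are scriptable through the bundled command-line
wrapper (`assoc`, `groupsize`, `network`, `simulate`, `synth`
subcommands):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mixnet.R", package = "mixnet"))')" \
    assoc dyad --in clusters.csv --pair Wb,Ze --m 10000 --seed 1 --out results/
```

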