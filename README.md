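# contrastnet

Mining **contrast subgraphs** from biological networks: node sets that are
densely connected in one network and sparsely connected in another network
defined over the same genes or proteins. Typical users are computational
biologists comparing coexpression networks between disease subtypes,
transcriptome-derived versus proteome-derived networks, or protein–protein
interaction maps of different cell lines — any setting where the question
is *which specific genes* change their connectivity, not just whether
global network statistics differ.

## The method

Given weighted networks *A* and *B* on shared nodes, form the signed
difference graph with edge weights `w_A(u,v) − w_B(u,v)` and maximize the
density objective

```
f(S) = (e_A(S) − e_B(S)) / |S|
```

— the densest-subgraph objective on a graph with negative weights, which
is NP-hard. `contrastnet` implements the greedy peeling heuristic:
iteratively remove the node minimizing `C·deg⁺(v) + deg⁻(v)`, keep every
intermediate set as a candidate, return the best one; sweep the scalar
`C > 0` over a grid and keep the overall best. The result is guaranteed to
reach at least `ρ*/2 − Δ/2` (with `ρ*` the true optimum and
`Δ = max_v |deg⁻(v)|`), which the test suite verifies against an exact
enumeration oracle. Top-k subgraphs come from iterating the miner while
zeroing each extracted set's within-set edges.

Around the miner sits the full comparison workflow:

* **Coexpression construction** — low-expression filter, `log2(x+1)`,
  Spearman correlation *or* compositionally robust proportionality (clr),
  and the unsigned WGCNA soft threshold `(0.5(1+ρ))^12`; networks stay
  complete (no hard cutoff).
* **Downstream statistics** — Mann–Whitney degree-distribution tests
  (exact under ties via a subset-count DP), Jaccard and one-sided Fisher
  overlap tests with an explicit universe, self-contained hypergeometric +
  Benjamini–Hochberg enrichment over GMT gene sets, strict `|log2FC| > 1`
  upregulation calls, and mRNA–protein agreement with Cohen's d.
* **Synthetic generators** — seeded planted-module network pairs and
  block-correlated two-condition expression matrices, so every claim is
  testable without external data.

Results are tibbles, fitted objects have `tidy()`/`glance()` methods, and
`autoplot()` covers degree distributions, enrichment dotplots and peel
traces.

## Worked example

Plant a 12-gene module coexpressed only in condition A, build both
networks, and mine:

```r
library(contrastnet)

sim <- planted_expression_pair(
  n_genes = 60, n_samples_a = 80, n_samples_b = 80,
  modules = list(list(genes = 12, loading = 0.85, active_in = "A")),
  noise_sd = 0.5, seed = 11
)
params <- coexpression_params(filter_max_low_frac = 0.25)
net_a  <- build_network(sim$expr_a, params)
net_b  <- build_network(sim$expr_b, params)
(res <- top_k_contrast(net_a, net_b, k = 2))
#> # A tibble: 4 × 6
#>    rank direction c_value objective  size nodes
#>   <int> <chr>       <dbl>     <dbl> <int> <list>
#> 1     1 A_over_B     0.25   0.998      12 <chr [12]>
#> 2     2 A_over_B     1      0.00666    15 <chr [15]>
#> 3     1 B_over_A     0.25   0.00470    14 <chr [14]>
#> 4     2 B_over_A     2      0.00438     2 <chr [2]>
```

The rank-1 A-over-B subgraph has density ≈ 1 — on soft-thresholded
weights in [0, 1] that means its 12 nodes are near-fully coexpressed in A
and not in B — while every other rank is at noise level (~10⁻³,
essentially the 2⁻¹² weight that independent genes get). It recovers the
planted module exactly, the degree shift between networks is significant,
and its overlap with the planted truth is far above chance:

```r
recovery_score(res[res$direction == "A_over_B", ], sim$modules$M1)
#> [1] 1
glance(degree_distribution_test(res$nodes[[1]], net_a, net_b))
#> # A tibble: 1 × 4
#>   n_nodes u_statistic     p_value method
#> 1      12         144 0.000000740 exact
fisher_overlap(res$nodes[[1]], sim$modules$M1, net_a$nodes)
#> # A tibble: 1 × 7
#>   overlap expected_overlap odds_ratio  p_value size1 size2 universe_size
#> 1      12              2.4        Inf 7.15e-13    12    12            60
```

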