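---
title: "Mining contrast subgraphs from omics-derived networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining contrast subgraphs from omics-derived networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrastnet)
```

## The problem

Comparing two biological networks defined over the same genes or proteins —
coexpression networks of two disease subtypes, mRNA- versus protein-based
coexpression, protein–protein interaction (PPI) maps of different cell
lines — raises a question that neither global structural statistics nor
network alignment answers: *which specific nodes* are responsible for the
largest difference in connectivity? A **contrast subgraph** is a node set
whose induced subgraph is dense in one network and sparse in the other.
Because the nodes keep their identity, the mined sets feed directly into
downstream biology: enrichment analysis, overlap tests between cohorts,
and expression follow-up.

## The model and the miner

Given weighted networks $A$ and $B$ on shared nodes $V$, form the signed
difference graph $D$ with $w_D(u,v) = w_A(u,v) - w_B(u,v)$. For a node set
$S$, write $e(S)$ for the sum of $D$-weights over within-$S$ pairs. The
objective is the density

$$f(S) = \frac{e_A(S) - e_B(S)}{|S|} = \frac{e(S)}{|S|},$$

i.e. the classic densest-subgraph objective on $D$. With non-negative
weights this is solvable in polynomial time; with signed weights it is
NP-hard, and `contrastnet` uses the **greedy peeling** heuristic: starting
from $V$, repeatedly remove the node minimizing the score

$$C \cdot deg^+(v) + deg^-(v), \qquad C \in (0, \infty),$$

where $deg^+$/$deg^-$ are the positive/negative parts of the signed
weighted degree, storing every intermediate node set $H_i$ as a candidate;
return the candidate maximizing $f$. The answer is guaranteed to reach at
least

$$\frac{\rho^*}{2} - \frac{\Delta}{2}, \qquad
\Delta = \max_v |deg^-(v)|,$$

with $\rho^*$ the true optimum; at $\Delta = 0$ the classic
$\tfrac12$-approximation is recovered. Since singletons have $f = 0$, the
returned objective is never negative. `peeling_bound()` exposes the bound,
and `brute_force_densest()` provides the exact optimum by subset
enumeration at test scale ($n \le 20$); the package's property tests check
the bound against this oracle on hundreds of random signed graphs.

Because no single $C$ dominates, `sweep_c()` reruns the peel over a grid
and keeps the best result. The default grid $\{0.25, 0.5, 1, 2, 4\}$ is
log-spaced around the neutral value 1: $C$ only rescales the positive part
of the removal score, so a small factor either way covers the regimes
where positive degrees should count less or more than negative ones.
Pushing $C$ beyond this range degenerates towards peeling by $deg^+$ or
$deg^-$ alone. The grid, like $k$ below, is an explicit knob, not a
reconstruction of any particular study's setting.

**Top-k extraction** (`top_k_contrast()`) iterates the sweep: after each
rank the within-set edge weights are zeroed in the current difference
graph — nodes are *not* deleted, so later ranks may reuse nodes but never
reuse an edge; the within-set *supports* of different ranks are provably
disjoint. Mining stops early once the best objective is $\le 0$, the value
any singleton attains, because such a "contrast" carries no signal. The
two contrast directions (dense in $A$ / dense in $B$) are mined
independently on $D$ and $-D$; the default $k = 2$ reflects that the first
one or two ranked subgraphs are usually the interpretable ones.

An **$\alpha$-regularized objective**
$e_A(S) - e_B(S) - \alpha\binom{|S|}{2}$ is provided by
`alpha_objective()` for scoring and reporting: the penalty makes every
pair lighter than $\alpha$ count against the set, so it can be used to
judge the size of a mined set. It is deliberately never optimized — the
miner is the peeling algorithm throughout.

### Determinism

All tie-breaks are fixed: node labels are canonically sorted (C-locale
radix sort) in every container; ties in the removal score drop the
lexicographically smallest label; ties among candidates prefer the
smaller set, then the lexicographically smaller one; ties across the $C$
grid prefer the smaller $C$. Identical inputs therefore give identical
outputs regardless of input row order, which the test suite asserts by
permuting inputs and by byte-comparing serialized reruns.

## Coexpression network construction

`build_network()` follows the standard WGCNA-style recipe:

1. **Filter** (`filter_low_expression()`): drop genes below an expression
   threshold (default 1, in FPKM/TPM-like units) in *strictly more than*
   `max_low` samples. The default `max_low = 50` is an absolute count
   appropriate to cohorts of several hundred samples and up; for smaller
   designs `max_low_frac` expresses it as a fraction of samples.
2. **Log transform** (`log_transform()`): $\log_2(x + 1)$. The base and
   offset are reproducibility conventions: Spearman correlation is
   rank-invariant, and proportionality is invariant to uniform rescaling
   of log variances, so neither choice affects the network.
3. **Association**: Spearman rank correlation (`spearman_matrix()`,
   pairwise-complete over missing values, average ranks under ties), or
   the **proportionality coefficient** (`proportionality_matrix()`)
   $\rho_p(i,j) = 1 - \mathrm{var}(a_i - a_j)/(\mathrm{var}(a_i) +
   \mathrm{var}(a_j))$ on centered-log-ratio (clr) profiles, which guards
   against spurious correlation induced by the compositional closure of
   relative-abundance data. The clr reference is the per-sample geometric
   mean over all retained genes, the common default; an alr-style
   reference is not offered.
4. **Soft threshold** (`soft_threshold()`): weight
   $(0.5\,(1+\rho))^\beta$ with $\beta = 12$, the unsigned WGCNA
   adjacency. Endpoints: $\rho = 1 \mapsto 1$, $\rho = -1 \mapsto 0$,
   $\rho = 0 \mapsto 2^{-12} \approx 2.4\times10^{-4}$. No hard cutoff is
   applied — the network stays complete, and the unsigned convention means
   negative correlations simply vanish; a signed variant is intentionally
   out of scope.

Degenerate genes (zero rank variance, or no complete observation pairs)
get all associations set to 0 with a warning rather than an error, since
single flat genes should not abort a 20,000-gene build. Genes with more
than 20% missing values are dropped before association — proteomics
matrices motivate the rule; the threshold is a pragmatic default, not a
fitted quantity.

## Downstream statistics

* `degree_distribution_test()` compares a node set's weighted degrees in
  the two networks with a two-sided Mann–Whitney U test. Degrees are
  taken **within the induced subgraph** by default, because within-set
  density is what the miner optimizes; `within = FALSE` switches to
  full-network degrees for the alternative reading. The test is *exact*
  up to $n + m \le 40$ via a subset-count dynamic program over doubled
  ranks — equivalent to enumerating all $\binom{n+m}{n}$ assignments, and
  still exact under ties, where the classical tables do not apply. Larger
  samples use the tie-corrected, continuity-corrected normal
  approximation. The permutation distribution of $U$ is symmetric about
  $nm/2$, so the two-sided exact p is the symmetric tail probability;
  on tie-free data this reproduces `stats::wilcox.test(exact = TRUE)` to
  machine precision (asserted in tests).
* `fisher_overlap()` tests the overlap of two sets against a declared
  universe (one-sided enrichment by default, matching the
  observed-versus-expected-by-chance framing; two-sided behind a flag)
  and reports the independence expectation $|s_1||s_2|/N$.
* `enrich()` is a self-contained over-representation analysis over a
  GMT-derived `gene_set_collection()`: hypergeometric upper-tail p per
  set, Benjamini–Hochberg adjustment across all tested sets, sets and
  query intersected with the universe first. The universe should be the
  genes present in both networks under comparison — the pipeline wires
  this automatically.
* `upregulated_genes()` implements the replicate-free fold-change call:
  up in A iff $\log_2(a+1) - \log_2(b+1) > 1$, strictly, so a two-fold
  change is *not* called.
* `expression_protein_agreement()` correlates each gene's mRNA and
  protein profile (Pearson, shared samples) and contrasts gene groups by
  Cohen's d with pooled Bessel-corrected SD; a zero pooled SD yields a
  signed infinity with a warning rather than an error, keeping degenerate
  toy inputs visible.

## The synthetic study conditions

The generators exist so that every claim the package makes is testable
without external data, and their defaults *are* the reference conditions
used throughout the tests and the acceptance script:

* `planted_contrast_pair()` plants a module (reference condition: 20 of
  200 nodes) whose within-module edge probability differs between the two
  networks ($p_{in,A} = 0.9$ versus $p_{in,B} = p_{bg} = 0.05$); all
  other pairs are background in both. A weighted mode draws Beta(5,2) /
  Beta(2,5) edge weights (means $5/7$ and $2/7$) so signed fractional
  weights, not just $\pm 1$, are exercised.
* `planted_expression_pair()` generates log-normal-like abundances: gene
  baselines $\log_2$-N(5, 1), a standard-normal latent factor per sample
  driving each active module with its loading, Gaussian noise on top, all
  exponentiated base 2. Reference condition: 200 genes, 200 + 200
  samples, one 25-gene module active in condition A with loading 0.8 and
  noise SD 0.5 — at these settings two module genes correlate at about
  $0.8^2/(0.8^2+0.5^2) \approx 0.72$, a realistic coexpression strength,
  and the end-to-end pipeline recovers the module at mean Jaccard
  $\ge 0.8$ over seeds (asserted in the acceptance suite for both
  Spearman and proportionality routes).

Randomness is Mersenne-Twister with a mandatory integer seed; the
caller's RNG state is saved and restored, and identical seeds give
byte-identical output on a given platform.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: library-size variation, count dispersion,
batch effects, compositional closure (module recovery under closure is
therefore *not* claimed; proportionality is offered because it is the
right measure when closure is present), realistic degree distributions of
PPI networks, and any correlation between module membership and
expression level.

## Numerical and scale choices

* Weights are 64-bit doubles; symmetry/diagonal checks and equality
  comparisons use an absolute tolerance of $10^{-9}$.
* Peeling maintains degrees and the running edge sum incrementally
  (subtracting the removed node's incident weights), so one run over a
  dense $n \times n$ matrix is $O(n^2)$; the objective of the selected
  candidate is recomputed from scratch on the stored node set, so any
  accumulated drift in the incremental sum cannot leak into reported
  objectives. A complete 2,000-node signed graph peels in a few seconds
  per $C$ value on one core (asserted with a wide margin in the tests).
  Coexpression matrices are dense by design ("no hard cutoff"); sparse
  PPI inputs simply arrive as edge lists and live in the same dense
  container at the scales the package targets.
* The test and acceptance problem sizes (10-node graphs for the
  enumeration oracle, 200-node planted networks over 50 seeds, 200-gene /
  400-sample expression studies over 25 seeds) were chosen so the whole
  property suite documents the method's behaviour in minutes on a laptop
  core while keeping the oracle checks exhaustive where exhaustiveness is
  the point ($2^{10}$ subsets; all Mann–Whitney splits with
  $n + m \le 12$; hypergeometric tables up to $N = 30$).

## Known limitations

* Greedy peeling is a heuristic: the $\rho^*/2 - \Delta/2$ bound is loose
  when $\Delta$ is large, and on adversarial signed graphs the mined set
  can be far from optimal even after the $C$-sweep. The package reports
  the fraction of exact hits against the enumeration oracle at test scale
  rather than pretending optimality.
* There is no confidence measure on a mined contrast subgraph. The
  supported substitute is robustness analysis: rerun under a different
  association measure or cohort and compare with `jaccard_index()` /
  `fisher_overlap()`.
* Directions are mined independently; edges zeroed in one direction's
  top-k loop are not zeroed in the other. Node sets from the two
  directions may therefore overlap.
* Identifiers are opaque case-sensitive strings; any probe-to-symbol or
  cross-species mapping happens upstream.

## A worked miniature

```{r example}
sim <- planted_expression_pair(
  n_genes = 60, n_samples_a = 80, n_samples_b = 80,
  modules = list(list(genes = 12, loading = 0.85, active_in = "A")),
  noise_sd = 0.5, seed = 11
)
params <- coexpression_params(filter_max_low_frac = 0.25)
net_a <- build_network(sim$expr_a, params)
net_b <- build_network(sim$expr_b, params)
res <- top_k_contrast(net_a, net_b, k = 2)
res
recovery_score(res[res$direction == "A_over_B", ], sim$modules$M1)

dt <- degree_distribution_test(res$nodes[[1]], net_a, net_b)
glance(dt)
```
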