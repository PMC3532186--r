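---
title: "Cluster-based interaction confidence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based interaction confidence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cappic)
```

## The model

Interaction confidence assessment asks, for every edge of a measured
protein–protein (or genetic) interaction network, how likely that edge
is to be a real interaction rather than an experimental artefact.
`cappic` answers this from topology alone, on the premise that
interactomes are modular: proteins participating in the same complex,
machinery or pathway are densely interconnected, so a real interaction
typically sits inside a module, while false positives connect
essentially random protein pairs and therefore tend to straddle
modules.

The unit being clustered is the *interaction*, not the protein. The
network $G$ is transformed into its line graph $L(G)$ — one node per
interaction, a link between two interactions when they share a protein
— and $L(G)$ is partitioned by Markov clustering (MCL). Because a
protein of degree $d$ appears in $d$ line-graph nodes, proteins can and
do span several interaction clusters; the clusters overlap in their
protein sets, which matches the biology of shared subunits and
moonlighting proteins.

For protein $p$ and interaction cluster $c$ define $L_{p,c}$ (links of
$p$ inside $c$), $L_{p,\cdot}$ (degree of $p$), $L_{\cdot,c}$ (size of
$c$) and $L_{\cdot,\cdot}$ (edges in the network). The *fidelity* of
$p$ to $c$ is the lower-tail cumulative hypergeometric probability

$$F_{p,c} \;=\; P(X \le L_{p,c}), \qquad
X \sim \mathrm{Hypergeom}\!\left(L_{\cdot,\cdot},\; L_{p,\cdot},\;
L_{\cdot,c}\right),$$

i.e. the probability that a random cluster of $L_{\cdot,c}$ edges would
contain at most as many of $p$'s edges as $c$ actually does. $F_{p,c}$
approaches 1 when $c$ is enriched in $p$'s interactions. Two
consequences worth knowing: for fixed $L_{p,c}$, smaller clusters give
larger fidelity; and the fidelity reaches exactly 1 whenever
$L_{p,c} = \min(L_{p,\cdot}, L_{\cdot,c})$, so a protein with all of
its links inside a cluster is maximally specific regardless of degree.

The confidence of interaction $l = (p_1, p_2)$ assigned to cluster $c$
is the plain product

$$\mathrm{confidence}(l) = F_{p_1,c}\cdot F_{p_2,c} \in [0,1],$$

with no renormalisation: an interaction is trustworthy only if *both*
partners are specific to the module that contains it. A hub whose edges
scatter over many clusters gets low fidelity in each, which is how the
model discounts promiscuous, likely-spurious connections without
removing hubs wholesale.

## Granularity self-tuning

MCL's inflation parameter sets how finely the walk matrix fragments:
values just above 1 give few large clusters, larger values many small
ones. Scores depend on this granularity, so it is chosen per network by
a built-in experiment:

1. Rewire a small fraction (default 3%) of the edges with
   degree-preserving double-edge swaps, yielding labelled false
   interactions inside an otherwise intact network.
2. Cluster and score that single rewired instance at each inflation of
   a coarse grid $\{1.1, 1.2, \ldots, 2.0\}$, then at a fine grid of
   step 0.025 within $\pm 0.1$ of the coarse optimum (clipped below at
   1.025; inflation must exceed 1).
3. At each inflation, compute the one-sided Wilcoxon rank-sum P-value
   for the alternative that surviving original links score higher than
   rewired links. The inflation minimising the P-value is optimal; ties
   break to the smallest (coarsest) inflation, consistent with the
   observation that useful granularities are coarse.
4. Score the *original* network at the chosen inflation — the optimum
   tunes the clustering resolution, a property of the network's module
   structure, and transfers from the lightly perturbed instance to the
   intact one.

One rewired instance is shared by all inflations, so the P-values are
compared on the same negative set. If some inflation yields a single
cluster, every score is 1 and no separation is measurable; that
evaluation gets P-value 1 by convention. The default 3% balances the
size of the false set (statistical power) against perturbing the very
modular structure being measured; 1–10% behave similarly in direction,
though at a few hundred edges the *argmin* itself is noisy (see
Limitations).

## Degree-preserving rewiring

A candidate swap replaces edges $(a,b), (c,d)$ with $(a,d), (c,b)$ or
$(a,c), (b,d)$ (orientation at random) and is rejected if it would
create a self-loop or duplicate edge, reconstitute an original edge,
touch an edge created by an earlier swap, or change the number of
connected components. Each swap destroys two real edges and creates two
false ones, so a fraction $f$ targets $\mathrm{round}(f\,m)$ rewired
edges rounded to the nearest even count. Rewired edges are excluded
from later swaps so they remain unambiguous negatives. The component
rule generalises "the network stays connected" to disconnected inputs;
whether connectivity should be enforced globally or per component is
not settled, and per-component is the conservative reading. A retry
budget of 100 draws per requested swap bounds the runtime; exhausting
it raises an error naming the swaps achieved, which signals a network
too constrained for the requested fraction (a star, paired triangles,
and similar degenerate shapes). `rewire_full()` applies the same moves
for $10m$ attempts without the original-edge and already-rewired
exclusions — the standard full configuration-style null model used for
random-pair baselines.

## Benchmarking harness

`roc_analysis()` repeats the reference-set construction (default 100
times; positives = surviving edges with evidence count ≥ 3, negatives =
rewired edges), scores each partially rewired instance, ranks positives
∪ negatives by decreasing confidence, and averages ROC curves
vertically on a fixed 101-point false-positive-rate grid. Tied scores
contribute fractionally (a single diagonal segment), making the exact
per-run area the rank-average Mann–Whitney statistic; the reported
`mean_auc` is the mean of per-run trapezoidal areas on the grid and so
equals the trapezoid of the mean curve identically. One grid-related
convention: a vertical jump exactly at FPR = 1 occupies half a terminal
grid cell, so the worst possible scorer integrates to 0.005 rather
than 0; the perfect scorer's jump at FPR = 0 is captured exactly and
integrates to 1. With the `cappic` scorer the granularity is tuned once
on the input network and reused for every rewired instance — the same
transfer argument as above; re-tuning per run would rewire an already
rewired network and multiply the cost twentyfold for no inferential
gain.

The common-neighbour baseline (`goldberg_roth_score()`) scores an edge
by $-\log_{10}$ of the upper-tail hypergeometric P-value of its
common-neighbour count given both degrees drawn from a universe of
`n_genes` (default 6000, a standard yeast genome figure). Edges whose
endpoints share no neighbour are left at 0 — the structural blind spot
that motivates cluster-based scoring in sparse networks.

## The synthetic generator, and what passing tests mean

`generate_planted_network()` samples a planted-partition (stochastic
block model) graph: $k$ modules of $s$ proteins, within-module edge
probability $p_{in}$, cross-module $p_{out} \ll p_{in}$, evidence count
3 on a configurable fraction of edges and 1 on the rest. It emulates
the one property the model actually consumes — pronounced modularity
with known ground truth — and deliberately not others found in real
interactomes: heavy-tailed degree distributions and hubs, hierarchical
or overlapping module structure, assay-specific sampling biases, or
informative evidence weights. Tests passing on these fixtures therefore
demonstrate correctness of the machinery and sane behaviour under
clean modularity; they do not certify performance on sparse,
hub-dominated maps, where the method itself is known to weaken (low
clustering coefficient means a weak topological signal).

Default study conditions used by the heavier tests and by
`scripts/acceptance.R`: a 6 × 20 network at $p_{in} = 0.3$,
$p_{out} = 0.005$ (≈ 370 edges, clustering coefficient ≈ 0.27 — the
density regime where topology-only scoring is informative), 3%
rewiring, 20 ROC repetitions, and a 4 × 20, $p_{in} = 0.25$ variant
for scan-focused checks (≈ 220 edges). These sizes keep the full suite
in the minutes range while leaving every statistic far from its
small-sample breakdown.

## Numerical and implementation choices

* **Hypergeometric CDFs** (fidelity and the common-neighbour tail) are
  computed by `stats::phyper`, which works in log space and is stable
  at interactome scale ($L_{\cdot,\cdot} \sim 10^5$); tests verify it
  against exact rational summation.
* **MCL arithmetic** is dense below 2000 line-graph nodes and sparse
  (`Matrix`) above. Defaults mirror the canonical implementation:
  expansion 2, self-loop weight 1, pruning threshold $10^{-5}$ (the
  per-column maximum is never pruned, so no column can empty),
  convergence when the largest entry change is ≤ $10^{-6}$, 200
  iterations cap (hitting it warns and returns the current state rather
  than failing). Columns are renormalised after inflation and again
  after pruning; column sums stay within $10^{-9}$ of 1 throughout,
  recorded on the result as a self-check. Clusters are the connected
  components of the limit matrix's non-zero structure, which resolves
  the rare overlapping-attractor degeneracy by merging — determinism
  without tie-break heuristics. Exact cluster-boundary agreement with
  any particular external MCL build is not guaranteed (pruning
  schedules differ) and nothing downstream depends on it.
* **Wilcoxon mode**: exact null distribution when both samples have
  ≤ 20 untied observations; otherwise the normal approximation with tie
  correction and continuity correction. Score vectors are heavily tied
  (many exact 1.0s), so the approximate path is the common one in the
  scan.
* **Tie-breaks** are deterministic everywhere: smallest inflation at
  equal P-values, lexicographic edge order in score bins and output
  rows, canonical (sorted-pair) edge identifiers.
* **Weighted clustering** (off by default): line-graph links combine
  edge evidence weights as $\sqrt{w_1 w_2}$. The geometric mean is
  symmetric and scale-balanced, but no canonical combination rule
  exists for this step — treat weighted results as this package's
  convention, not a community standard. The unweighted default keeps
  results comparable with weight-free protocols.
* **Duplicate input rows** merge by maximum weight/evidence
  (order-independent, conservative); self-loops are dropped with a
  warning.
* **Degenerate inputs**: a single-edge network clusters into one
  singleton cluster and scores 1.0; whole components that form single
  clusters score 1.0 exactly (the CDF hits its support bound); networks
  too constrained to rewire fail loudly rather than silently
  under-rewiring.

## Known limitations

* At a few hundred edges, the Wilcoxon P-value surface over inflation
  has a broad, flat valley, and small rewiring fractions provide very
  few negatives (1% of 370 edges is 4). The *location* of the minimum
  then fluctuates by several fine-scan steps between rewiring draws,
  even though the induced clusterings — and hence the scores — change
  far less. On interactome-scale inputs (thousands of edges) the
  negative set is 1–2 orders of magnitude larger and the estimate
  sharpens correspondingly.
* A degree-preserving swap can, by chance, create an edge between two
  proteins of the same module. Such an edge is labelled false but is
  topologically indistinguishable from a real within-module
  interaction and scores accordingly; benchmark AUCs therefore slightly
  underestimate true discrimination, and strict per-bin monotonicity of
  bin summaries can break on a single such edge.
* The method presumes modularity. On networks with clustering
  coefficients near random (sparse two-hybrid maps), the signal the
  fidelity measures is weak and scores should be interpreted
  cautiously, or combined with orthogonal evidence.
* Scores are enrichment products, not calibrated probabilities; they
  order interactions within one network and should not be compared
  across networks of very different size or density.
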