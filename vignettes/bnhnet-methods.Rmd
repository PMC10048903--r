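---
title: "Methods: network topology, complex detection and regulatory motifs in bnhnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network topology, complex detection and regulatory motifs in bnhnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnhnet)
```

bnhnet implements the network side of a disease-interactome study: given a
protein–protein interaction (PPI) network and signed regulatory edge tables,
it characterises the network's global organisation, extracts its most
influential nodes, detects dense subnetworks, quantifies how the influential
nodes couple those subnetworks, and classifies the three-node regulatory
circuits (feed-forward and feedback loops) wired around them. This vignette
explains the models and conventions, the tunable parameters, what the
synthetic generators do and do not emulate, and the numerical choices.

## Topological model

The PPI network is an undirected simple graph: self-loops and duplicate
edges are dropped at read time (a message reports counts), and identifiers
are trimmed; an optional normalisation upper-cases gene symbols and
canonicalises miRNA ids (`hsa-miR-...`), since real exports mix cases.

Six per-node quantities drive the analysis:

* **degree** `k`;
* **clustering coefficient** `C = 2m / (k(k-1))`, with `m` the number of
  edges among the node's neighbours; nodes of degree < 2 are assigned 0
  (the quantity is otherwise undefined, and 0 keeps them out of log–log
  fits, which use strictly positive values only);
* **neighbourhood connectivity**: the mean degree of the node's neighbours;
* **betweenness**: the fraction of shortest paths passing through the node,
  normalised by `(n-1)(n-2)/2` so values lie in `[0, 1]` — published
  bottleneck tables print values on this scale;
* **closeness**: computed per connected component as
  `(reachable - 1) / sum of geodesic distances`. The textbook `N / Σd` form
  is undefined on disconnected inputs; the per-component convention is the
  one implemented by standard network tools and degrades gracefully, so it
  is used here (isolated nodes get 0);
* **eigenvector centrality**: the principal eigenvector of the adjacency
  matrix, all entries non-negative, scaled to unit L2 norm.

Eigenvector centrality is computed by a shifted power iteration: iterating
`x ← (A + I) x` with an L2 normalisation each sweep, from a uniform start
vector, tolerance `1e-10` in the sup norm, at most 1000 sweeps. The `+ I`
shift makes every eigenvalue of the iteration matrix positive, so the
method converges on bipartite graphs too (plain power iteration oscillates
there because `-λ_max` is also an eigenvalue). The iteration is fully
deterministic, which keeps pipeline outputs byte-identical across runs —
Lanczos-based routines are faster but nondeterministic in the last bits.
The test suite checks betweenness, closeness and eigenvector against
brute-force reference implementations (explicit geodesic counting and a
dense eigendecomposition) to `1e-9` on hundreds of random small graphs.

### Power-law fits

All scale diagnostics are ordinary least squares on log–log axes, applied
to **per-degree means** (one point per observed degree), not to per-node
scatter: this matches how the field plots `P(k)`, `C(k)`, `CN(k)`,
`C_B(k)`, `C_c(k)` and `C_E(k)`, and stops high-frequency low-degree nodes
from dominating the fit. Degrees or means that are zero are excluded
(log undefined); fewer than three positive points is an error; a constant
metric is reported as slope 0 with a `degenerate` flag rather than an
undefined correlation. The returned slope is signed (`y ~ k^s`), so a
decaying law has a negative slope, and `pearson_r` is the correlation of
the log–log points. Maximum-likelihood tail estimation is a different
instrument answering a different question (tail exponent of a
distribution); it is deliberately not the fitting method here.

## Key nodes: hubs, bottlenecks, bottleneck-hubs

Hubs are the strict top-`n` nodes by degree and bottlenecks the strict
top-`n` by betweenness (`n = 10` by default, the conventional top tier in
interactome studies). Ties are broken by metric descending, then node id
ascending — deterministic and label-equivariant — and tied tails are *not*
expanded, matching the fixed "top 10" convention. Bottleneck-hubs are the
intersection, ordered by hub rank. A replay reader accepts a published
two-list table directly, so printed worked examples can be re-analysed
without the source network.

## MCODE complex detection

The molecular complex detection algorithm is implemented from scratch:

1. **Vertex weighting.** For each vertex, take its closed neighbourhood
   (the vertex plus neighbours), find the highest k-core of that subgraph,
   and set `weight = k_max × density(highest k-core)`, with simple density
   `2E / (n(n-1))`. An isolated vertex weighs 0; a vertex whose closed
   neighbourhood is a single edge weighs 1.
2. **Expansion.** Seeds are consumed in weight-descending order (id
   tie-break). From an unassigned seed, a breadth-first expansion admits
   unassigned neighbours whose weight is at least
   `seed_weight × (1 - node_score_cutoff)`, to at most `max_depth` levels.
   Every vertex joins at most one complex.
3. **Post-processing.** Complexes with no `k_core_filter`-core are
   discarded; optional *fluff* adds unassigned boundary vertices whose
   closed-neighbourhood density exceeds `fluff_density_cutoff`; the
   *haircut* then iteratively removes singly-connected members (equivalent
   to taking the 2-core), and is idempotent.

Defaults are the canonical ones: cutoff 0.2, haircut on, fluff off with
density cutoff 0.1, 2-core filter, depth 100. Complexes are ranked by
`score = density × n = 2E/(n-1)`; a clique of `n` nodes scores `n`, and a
31-node, 422-edge complex scores 28.13 — the package's headline check.

One consequence of the greedy semantics is worth stating: two equally dense
cliques joined by a *direct* bridge edge merge into one complex, because
the bridge endpoint clears the weight threshold and expansion continues
through it. That is the documented behaviour of the canonical
implementation, and the tests assert it explicitly. Separate recovery is
guaranteed when dense regions are attached through a sparse background
(the planted-clique benchmark), where recovery is exact at the default
parameters.

By default the top five complexes are carried into the crosstalk stage
(`retained_complexes = 5`), mirroring the usual practice of analysing a
handful of top-scoring subnetworks; the count is a pipeline parameter.

## Crosstalk and the key mediator

The interaction strength between a bottleneck-hub and a subnetwork counts
the subnetwork members adjacent to it in the **full** network, excluding
the node itself. Two consequences, both deliberate: a member of an
`n`-node subnetwork can score at most `n - 1`, and a bottleneck-hub outside
a subnetwork still scores through its boundary edges. Row totals over
subnetworks rank the bottleneck-hubs; the maximal row (ties by id) is the
key mediator.

## Signed regulatory networks and motifs

Regulation comes in four directed signed layers: TF→gene, TF→miRNA,
miRNA→gene and gene→miRNA (a hub gene acting upstream of a miRNA). Signs
are +1 (activation) or -1 (repression); sign tokens `activate/repress/+/-/
+1/-1` are accepted, anything else is rejected with its row number, and
unsigned miRNA→target edges are *not* defaulted silently in the readers —
repression defaults exist only in the synthetic generator, where they are a
documented modelling choice (miRNA action is predominantly repressive).
A node may hold the TF and gene roles simultaneously (motif roles are
assigned per edge layer, so the same gene can be the target of one loop and
the TF of another); a miRNA sharing any other role is a validation error.

A feed-forward loop (FFL) is a triple with all three edges TF→miRNA,
miRNA→gene and TF→gene. It is **coherent** when the direct sign equals the
product of the indirect ones, and typed by the standard eight-row table
(signs ordered TF→miRNA, miRNA→gene, TF→gene):

| type | signs | coherence |
|------|----------|-----------|
| C1 | +,+,+ | coherent |
| C2 | −,−,+ | coherent |
| C3 | +,−,− | coherent |
| C4 | −,+,− | coherent |
| I1 | +,−,+ | incoherent |
| I2 | −,−,− | incoherent |
| I3 | +,+,− | incoherent |
| I4 | −,+,+ | incoherent |

Published motif narratives sometimes label loops inconsistently with their
own sign data; the sign-product rule above is normative here, and the type
labels follow the standard nomenclature rather than any ad-hoc naming.
Enumeration joins the three layer tables on shared endpoints (so it scales
with realised two-paths); an exported cubic brute-force scan provides the
independent reference, and the test suite requires exact agreement between
the two on dozens of random networks. Feedback loops are reciprocal
gene↔miRNA pairs, reported with the product sign (-1 = negative feedback).

Consensus miRNA targets across prediction sources keep pairs supported by
at least `min_support` sources (default: all of them, the strict
intersection used when combining two predictors and one validated
database); support counting is monotone by construction.

## Enrichment

Over-representation uses the hypergeometric upper tail
`P(X ≥ k)` for the overlap of a query with each term, restricted to a
background that defaults to the union of all annotated identifiers (the
"only annotated" domain convention). Multiple testing uses
Benjamini–Hochberg — the proprietary multi-layer correction of the popular
web service is not reimplemented, and BH is the standard local equivalent.
Odds ratios come from the 2×2 table with a Haldane 0.5 correction when a
cell is zero (a zero overlap is reported as odds ratio 0). The default
reporting threshold is adjusted p ≤ 0.05.

## Synthetic generators: what they emulate

All generators take a mandatory seed and are reproducible to the byte.

* `gen_scale_free` grows a preferential-attachment graph (heavy tail,
  connected). Pure preferential attachment is asymptotically
  degree-uncorrelated, so it does **not** show the disassortative mixing
  real interactome exports do; passing `exponent` switches to the static
  fitness model whose simple-graph structural cutoff produces genuine
  disassortativity. The analysis drivers use the latter regime as the
  interactome stand-in.
* `gen_hierarchical` builds a deterministic clique-tree: modules are
  `base`-cliques arranged in a tree of depth `levels`, a depth-`d` module
  having `2^(levels-d)` children, every child-module node wired to the
  parent module's hub. Low-degree members sit in closed cliques (`C = 1`)
  while hubs accumulate degree in geometric steps over ever-sparser
  neighbourhoods, which yields the hierarchical signature `C(k) ~ k^-1` by
  construction. The branching schedule is chosen so the largest hub stays
  below the structural cutoff `sqrt(2E)`: replica-style constructions that
  concentrate most edges on one centre pin the hub's clustering near its
  density ceiling, so even their degree-preserving rewirings keep a steep
  `C(k)` decay, and the rewired null stops being informative about
  hierarchy. With the clique-tree, the hierarchy diagnostic is a clean
  contrast: the generated graph fits a clustering slope steeper than -0.7,
  while the mean slope over an ensemble of degree-preserving rewirings
  (30 in the tests; single rewirings are noisy because only a handful of
  degree classes exist) sits near zero.
* `gen_planted_clusters` embeds cliques in a sparse Erdős–Rényi background
  with Bernoulli attachment edges, returning the planted membership as
  ground truth — the recovery benchmark for MCODE.
* `gen_signed_regnet` samples each regulatory layer independently and can
  plant FFLs of requested types on dedicated nodes (planted edges overwrite
  colliding background edges). Ground truth is recomputed from the final
  edge table by the brute-force scan, so it includes incidental background
  motifs as well as planted ones.

None of the generators mimic the confidence-score distributions, identifier
vocabularies or annotation biases of real databases. Passing tests
therefore demonstrate algorithmic correctness under the assumed statistical
regimes — scale-free tails, nested modularity, planted density, random
signed layers — not robustness to the noise structure of any particular
resource.

## Problem sizes and runtime choices

The test and driver workloads are sized for quick, repeatable runs:
interactome stand-ins of 2000 nodes, a 525-node hierarchical graph
(`levels = 4, base = 5`), planted-clique benchmarks around 200 background
nodes, regulatory layers of ~10–12 nodes per role, 200 brute-force oracle
graphs of up to 8 nodes, and 50 random motif networks. These sizes give the
property suites enough statistical room (e.g. the rewired-ensemble mean
stabilises well inside its acceptance band) while keeping a full run in the
tens of seconds.

## Known limitations

* Confidence scores on interaction edges are not modelled; networks are
  unweighted (score-aware filtering would be a natural extension of the
  readers).
* The MCODE implementation covers the canonical undirected, unweighted
  algorithm; directed or weighted variants are out of scope.
* No statistical null is attached to crosstalk totals (none is standard),
  and motif counts are not compared against rewired ensembles.
* The enrichment stage is a local ORA; it does not reproduce web-service
  pipelines, their gene-set libraries, or composite scores built on them.
* TF→miRNA edges with unknown sign must be supplied explicitly signed or
  left out; the package does not guess regulator signs.
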