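---
title: "Methods: network prioritisation and topological analysis with crohnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network prioritisation and topological analysis with crohnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crohnet)
```

## The analysis in one paragraph

Genome-wide association studies nominate many candidate genes for complex
diseases such as Crohn's disease, but most candidates are bystanders.
`crohnet` implements a network strategy for narrowing them down and for
characterising the result: candidate genes are ranked by a random walk
with restart (RWR) seeded at a *training set* of genes with established
disease roles, the diffusion ranking is intersected with an externally
produced relatedness ranking to form a *consensus* prioritised list, and
the *disease sub-network* — every interaction touching a prioritised
gene — is then examined for the structural signatures one expects of a
genuine disease module: elevated density, hub proximity, motif
composition against a degree-preserving null, attack fragility, and
topological segregation of functional classes.  Because the real inputs
(interaction snapshots, literature rankings, expression studies,
annotation services) are external and version-dependent, the package
ships a synthetic-data generator with a planted disease module so that
every stage is testable end to end, with known ground truth.

## The random walk with restart

The walker iterates

$$p^{(t+1)} = (1-r)\,W p^{(t)} + r\,e,$$

with $W$ the column-normalised adjacency matrix (a walker at a node
leaves along each incident edge with equal probability), $e$ uniform
over the training genes present in the network, and restart probability
$r$.  The stationary $p$ scores every gene by its diffusion proximity to
the training set; candidates are then selected either as the top $k$ or
by a probability threshold (`select_by_steady_state()`).

Numerical choices:

* **Restart probability** `r = 0.5` by default.  The value is exposed
  everywhere; results are stable over a broad range because only the
  candidate *ranking* is consumed.  Increasing $r$ provably concentrates
  mass on the training set (a property the tests verify on an $r$ grid).
* **Convergence** is declared when the L1 difference between successive
  vectors drops below `tol = 1e-10`, with `max_iter = 10000`; the
  `converged` flag is always reported.  `rwr_exact()` solves
  $(I - (1-r)W)p = re$ directly and serves as the reference
  implementation — the test suite requires the two routes to agree to
  within $10^{-8}$ in L1 on random graphs.
* **Degree-zero nodes.** A column-stochastic $W$ is undefined for an
  isolated node.  We give such nodes a self-retaining column (their mass
  stays put between restarts), which keeps $\lVert p\rVert_1 = 1$ exactly
  at every iteration — with a zero column, an isolated training gene
  would leak mass and the conservation invariant would fail.  Walker
  mass still never crosses between components.

**Consensus rule.** "Consensus of two prioritisation routes together
with the training set" admits several readings; we use the weakest one —
the intersection of the diffusion selection and the external selection,
united with the training set — and expose a `union` mode.  Training
genes are retained in the consensus whether or not the two selections
rediscover them; an optional `nodes` argument restricts the final list
to genes present in the interaction network.  The external route
(ranked relatedness list with p-values) is consumed as a file; producing
it (e.g. by literature text mining) is outside the package's scope.

## The disease sub-network

`extract_disease_network()` keeps every interaction with at least one
endpoint in the prioritised list, so first neighbours enter the network
and indirect interactions among disease proteins are retained.  Nodes
are flagged `prioritised` vs `neighbour`, because enrichment questions
distinguish the prioritised proteins from the full disease-network
protein set.  The node set is exactly the set of retained-edge
endpoints: a prioritised gene with no interactions contributes nothing.

## Topology against an Erdős–Rényi ensemble

`er_ensemble_compare()` draws $G(N, M)$ graphs with the network's exact
node and edge counts and reports z-scores and two-sided normal p-values
for mean degree, mean local clustering, mean shortest path, diameter,
density and component count.  Mean shortest path and diameter are
computed within the giant component, since they are undefined for
disconnected graphs; this is recorded in the report.  With edge count
fixed, density has zero ensemble variance — its z is reported as
undefined rather than infinite.  The default ensemble size is 100.

The topological coefficient of a node $n$ with degree $k_n \ge 2$ is
$\mathrm{TC}(n) = \operatorname{mean}_m J(n,m)/k_n$, the mean running
over all nodes $m \neq n$ sharing at least one neighbour with $n$, and
$J(n,m)$ counting shared neighbours plus one if $n$ and $m$ interact.
On the 4-clique every partner gives $J = 3$, so $\mathrm{TC} = 1$; on
the 4-cycle the sole partner of a corner is the opposite corner
($J = 2$, $k = 2$), so $\mathrm{TC} = 1$ as well — the test suite pins
these hand-enumerated values.

## Motifs and the switching null

The census counts every **connected induced** subgraph on 3 or 4 nodes
once, keyed by the classic decimal subgraph id: the symmetric adjacency
matrix is read row-major as a bit string and minimised over all $k!$
node permutations.  Under this convention the 3-path is id 78, the
triangle id 238 and the 4-clique id 31710, which is how motif ids are
reported in the motif-detection literature and lets results be compared
across tools.  The null model is degree-preserving edge switching
(double-edge swaps rejecting loops and duplicates), 10 swap trials per
edge and 100 randomised networks by default, and calls use the
conventional threshold $|z| \ge 2$.  A class with zero null variance
whose real count matches the null mean is `neutral`; a zero-variance
class whose count differs is flagged `divergent` rather than assigned
an infinite z.

Per-protein **motif participation** enumerates every connected induced
k-subgraph (an ESU-style exhaustive enumeration) and counts, for each
gene, the instances of motif-called classes containing it — the route
by which the most motif-associated disease proteins are identified.
Counting only motif-called classes is the default; a flag counts all
classes.  Because exhaustive enumeration of 4-subgraphs grows steeply
around hubs, the default pipeline tabulates participation for
3-subgraphs.

## Failure-attack robustness

`removal_trajectory()` deletes nodes in batches of
$\lceil \text{step} \cdot N\rceil$ — uniformly at random (failure), by
descending or ascending degree (attack), or restricted to a supplied
gene set — and records surviving interactions and cumulative
*secondary extinctions*: nodes never deliberately removed whose degree
has fallen to zero.  The degree ordering is computed once on the intact
network (static ordering, deterministic with lexicographic tie-breaks);
a `recalculate` flag switches to the adaptive variant that re-ranks
survivors before each batch.  Static ordering is the common baseline
and makes attack curves reproducible without a seed.

## Topological segregation of functional classes

For a class $j$ with $n_j$ members in a network of $N$ nodes, the shell
fraction $S_i(d)$ of member $i$ is the proportion of nodes at shortest
path distance $d$ from $i$ that belong to the class (the focal node is
never counted), $\langle S^j(d)\rangle$ averages over members with
non-empty shells, and the scalar index averages the normalised ratios
over $d = 1 \dots d_{max}$.  We normalise by the class frequency among
*non-focal* nodes, $(n_j-1)/(N-1)$: conditioned on the focal member,
the remaining $n_j - 1$ members fall among the other $N - 1$ nodes, so
under random labels the expected ratio is exactly 1 at every $d$ — at
$N \approx 10^4$ this is numerically indistinguishable from the
classical $n_j/N$, but at the package's test scale ($N = 500$) the
uncorrected form is visibly biased below 1.  $d_{max}$ defaults to the
largest distance at which at least half the class still has a non-empty
shell (deep shells are dominated by a handful of eccentric members);
both the coverage fraction and a fixed $d_{max}$ are exposed, and the
full per-distance profile is always returned so any other aggregation
can be recomputed.  Averaging the per-distance ratios is the default;
`ratio_of_means` divides the distance-averaged shell fraction by the
class frequency instead.  Classes with fewer than `min_size = 5`
members in the network are skipped as too small to characterise.

## Enrichment statistics

* **Hubs** are nodes with degree strictly above the network mean — the
  convention used for single-protein hub-neighbour questions — and the
  same rule serves for population-level hub over-representation, with
  degree always measured on the full proteome network.
* **Hypergeometric** upper-tail p for hub over-representation in a gene
  list; **Fisher's exact test** (two-sided = sum of no-more-probable
  tables) for differential-expression enrichment and per-protein
  hub-neighbour contingency; **binomial** upper-tail with Bonferroni
  correction for functional-category over-representation.  All three are
  checked against exhaustive enumeration oracles in the tests.
* The binomial success probability is the class frequency within the
  *annotated* reference (the classified universe), matching a reference
  list defined as "all classified genes".  Taking the frequency over an
  only partially annotated reference while restricting $n$ to annotated
  list genes would inflate the type-I error whenever annotation coverage
  is incomplete; with the classified-universe form the empirical type-I
  error is nominal, which the tests verify by simulation under the
  uniform null.
* The DE call threshold is an adjusted p below 0.05 by default.

## The synthetic study

`crohnet_scenario()` fixes the study conditions; `simulate_study()`
generates all artifacts deterministically from one seed.

| parameter | default | what it encodes |
|---|---|---|
| `n_nodes`, `m` | 500, 2 | preferential-attachment interactome; heavy-tailed degrees |
| `triadic` | 0.1 | one triadic-closure trial per node; degree-dependent clustering |
| `module_size`, `module_density` | 30, 0.3 | planted disease module, an order of magnitude denser than the ~0.008 background |
| `n_training`, `n_decoys` | 10, 30 | known disease genes; off-module decoys among the candidates |
| `ranking_noise` | 0.2 | noise of the external relatedness score around the membership indicator |
| `de_sensitivity`, `de_background` | 0.8, 0.05 | P(called DE) inside/outside the module |
| `n_classes`, `class_cohesion` | 10, 0.9 | functional classes grown as connected patches |

Preferential attachment (each new node attaches to `m` existing nodes
with probability proportional to degree) rather than Erdős–Rényi was
chosen deliberately: hub-attack fragility and degree-dependent
clustering — both properties the analysis is meant to detect — are
genuine features of such graphs.  With `triadic = 0` the edge count is
exactly $\sum_{i=2}^{n}\min(m, i-1)$, which the tests assert as a
construction audit.  Ranking p-values are rank-transforms
($p = \text{rank}/N$), not model-based — the pipeline only thresholds
them.  Class labels grow by seeded label-spreading: with probability
`class_cohesion` a class claims an unlabelled neighbour of its members,
otherwise a random unlabelled node; cohesion 0 is exactly the uniform
random-label null.

What the generator does **not** emulate: assortativity and clustering
levels of curated interactomes, false-positive/false-negative structure
of interaction detection, linkage disequilibrium between candidate
loci, realistic expression covariance, overlapping (non-exclusive)
annotation classes.  Passing tests therefore demonstrate correctness of
the algorithms and recoverability of planted structure under the stated
conditions — not performance on any particular real interactome.

## Problem sizes and determinism

The test suite and the bundled pipeline run at deliberately moderate
sizes — a 500-node interactome (tests of the attack-fragility property
use 1000–5000 nodes), ensembles of 50–100 null networks, exact-test
oracles up to table total 40, brute-force subgraph oracles up to 25
nodes — chosen so the whole suite completes in about a minute while
keeping every Monte-Carlo margin comfortable.  Every source of
randomness flows from explicit seeds: scenario operations use fixed
offsets from `scenario$seed`, pipeline stages derive their seeds
deterministically from the global configuration seed, and a pipeline
rerun with the same configuration is byte-identical.

## Known limitations

* Motif analysis is restricted to sizes 3 and 4 (exact enumeration;
  no sampling estimator), and directed graphs are out of scope.
* The segregation index is reported without a built-in permutation
  p-value; the label-permutation null is easy to simulate (see the test
  suite) but is not part of the returned object.
* Identifier handling is deliberately opaque: no Entrez/UniProt/symbol
  mapping is performed, and identifiers are case-sensitive strings.
* The external relatedness ranking and the differential-expression
  table are consumed, never produced: text mining and microarray
  analysis are upstream tools with mature implementations of their own.
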