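---
title: "Interaction networks as metric spaces: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction networks as metric spaces: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinmetric)
```

## The model

`pinmetric` analyses an undirected simple graph `G = (V, E)` as a metric
space under hop distance `d(u, v)`, the length of a shortest path. All
edges have unit length: interaction confidence scores, directions and signs
are deliberately ignored, and self-interactions are dropped on load (they
play no role in distances). Because distances are unit-weighted, one
breadth-first search per source computes exactly the same shortest-path
distances a Dijkstra run would, at lower cost; the eccentricity engine is
therefore an all-source BFS written in C++ and is exact — no landmark
sampling, no bound-based pruning shortcuts are applied without verification
against brute force (the test suite cross-checks against Floyd–Warshall and
an independent graph library).

From the eccentricities `ecc(v) = max_u d(v, u)` we derive the radius
(minimum), diameter (maximum) and the **topological centre**: *all* nodes
attaining the radius. Real interaction networks usually yield a single
centre, but that is an empirical finding, not an assumption — the API
returns the full centre set, and zone decomposition accepts any centre set.

**Zones.** Zone `k` is the set of giant-component nodes at distance exactly
`k` from the nearest centre node (multi-source BFS layering; zone 0 is the
centre itself). With a single centre, the maximum zone index equals the
radius. Two invariants follow and are asserted widely in the tests: zone
indices of adjacent nodes differ by at most one, and every node of zone
`k >= 1` has a neighbour in zone `k - 1`.

**Connectivity.** Eccentricity is infinite across components, so the
analysis is defined on a connected graph only. The pipeline extracts the
giant (largest) component explicitly and errors on disconnected input
rather than restricting silently; behaviour on the full disconnected graph
is intentionally undefined.

## Per-zone statistics and their conventions

- **Degrees are whole-graph degrees.** A zone-summary row reports the
  degree each node has in the full (giant-component) graph, not in the
  zone's induced subgraph. A node attached only to the centre has induced
  degree 0 but whole-graph degree 1; published per-zone tables are
  consistent only with the whole-graph reading, which we adopt throughout.
- **Quills** are operationalised as nodes of whole-graph degree exactly 1,
  tallied per zone. A looser path-based reading ("a fringe subgraph that
  eventually becomes a path ending in a degree-1 node") exists; we use the
  degree-1 reading because it is unambiguous, matches how quill counts are
  tabulated in practice, and makes the synthetic generator's bookkeeping
  exact. This choice is deliberate and documented rather than silently
  assumed.
- **Hub threshold.** The top fraction (default 5%) of the degree
  distribution is capped at `ceiling(fraction * n)` nodes: the threshold is
  the smallest realised degree `d` such that at most that many nodes have
  degree `>= d`, and all ties at `d` are admitted. The realised hub count
  can therefore sit below the cap (heavy ties push the threshold up — in
  the extreme of an all-tied regular graph nobody is admitted) but never
  above it. Percentages are reported against the total admitted hubs and
  sum to exactly 100 when any hub exists. Zone 0 is included in the tally:
  the centre is typically itself a hub, and including it keeps the
  percentages exhaustive.
- **Node exclusion.** Suspect substructures (e.g. a dense complete subgraph
  of paralogues) can be removed before hub analysis; exclusion removes the
  nodes from the graph (recomputing degrees) before thresholding and
  tallying, which is the only reading under which "removing" a subgraph
  changes the threshold.
- **Zone–degree correlation** is the Pearson correlation between zone index
  (1..max) and zone mean degree, requiring at least 3 zones; constant mean
  degrees make it undefined and return `NA` with a warning rather than a
  fabricated value.
- **Display rounding.** Mean degrees are kept at full precision in all
  machine-readable output; any rounding is for display only.

## The R-MAT null model

Random power-law graphs are generated with the recursive-matrix (R-MAT)
procedure: each candidate edge descends `k = ceiling(log2(n_target))`
quadrant choices of the `2^k x 2^k` adjacency matrix with probabilities
`(a, b, c, d)`, self-loops and duplicate undirected pairs are resampled, and
matrix indices left untouched are dropped. Consequences worth knowing:

- The realised order is typically below (occasionally above) `n_target` and
  varies across seeds — matched replicates are *size*-exact in edges and
  only approximately matched in nodes, which mirrors how such nulls behave
  in practice.
- Resampling duplicates (rather than dropping them) makes the edge count
  exact; the sampler errors if `max_attempts` candidate draws cannot
  realise `m_target` distinct edges.
- Defaults `(a, b, c, d) = (0.57, 0.19, 0.19, 0.05)` are the canonical
  R-MAT parameter set for skewed power-law-like graphs and are exposed as
  arguments everywhere. The choice matters: stronger diagonal skew
  concentrates edges on few rows, producing very large hubs, more small
  satellite components and many degree-1 nodes adjacent to central hubs.
  Published contrasts built with milder-skew generators (web-graph style
  settings nearer `a + b ≈ 0.6`) show fewer components, smaller maximum
  degrees and no central quills; with the canonical defaults this package's
  replicates reproduce the *direction* of every contrast (smaller diameter
  than a core–periphery reference, multiple tied centres, heavy-tailed
  degrees) but not the component and central-quill counts of milder
  settings. We keep the canonical defaults because no authoritative record
  of the milder settings exists, and tuning the null's parameters to match
  a desired table would defeat its purpose as a null.
- Replicate `i` of a matched batch uses seed `master_seed + i`; all
  randomness flows through explicit seed arguments (`withr::with_seed`), so
  batches are byte-reproducible and no global RNG state is touched.

## Over-representation analysis

Each (zone, gene set) pair is tested one-sided for over-representation:
with a universe of `N` annotated nodes, `K` of them in the set and `n` in
the zone, the p-value is `P[X >= k]` for hypergeometric `X` (zero overlap
gives exactly 1; a zone spanning the whole universe can never be enriched).
Depletion is not tested. Two conventions are configurable because no single
standard exists:

- **Universe**: by default the giant-component nodes appearing in at least
  one gene set, mirroring enrichment services that condition on annotated
  genes; an explicit universe can be passed instead (the planted-recovery
  tests pass the full node set, under which the planted set's zone
  proportion estimates the planted membership rate directly).
- **Correction**: Benjamini–Hochberg across all (zone, set) pairs by
  default, Bonferroni optionally; significance cutoff 0.01 on the corrected
  p-value, following common practice for pathway enrichment.

The specialisation table reports, per zone, the `top_n = 4` significant
sets with the proportion of the zone's (in-universe) members they cover —
high coverage by few sets is what "functionally specialised" means
operationally here.

## The synthetic world

`planted_core_periphery()` emulates the features of real interaction
networks that the pipeline must detect, with exact ground truth:

- one designated centre adjacent to every zone-1 node;
- every zone-`k` node wired to at least one zone-`(k-1)` non-quill node,
  which pins its distance from the centre to exactly `k` (edges only ever
  connect zones differing by at most one, so no shortcut can form);
- within-zone edges among non-quill members at a per-zone density chosen to
  decrease outward;
- exact per-zone quill counts: planted quills receive a single upward edge
  and nothing else, and any non-quill node left at degree 1 by the density
  draw gets one repair edge (a second previous-zone parent, else a
  within-zone partner) so the degree-1 census equals the planted quill map
  exactly — without the repair the bookkeeping oracle would fail at low
  densities;
- centre uniqueness enforced by rejection sampling (bounded at 100 tries):
  the candidate graph is accepted only when the recomputed centre is
  exactly the planted node, matching the empirically typical single-centre
  case while keeping the construction simple.

Defaults (zones 50/200/100, densities 0.3/0.02/0, quills 0/20/100) are a
desk-scale caricature of the published core–periphery profiles: a dense
zone 1 without quills, a moderately sparse zone 2 with some quills, and a
pure-quill fringe. What the generator does *not* emulate: power-law degree
tails (its zone-1 degrees are binomial-ish), cross-zone edges beyond
parent links, biological module structure, and assortativity. A green
recovery test therefore establishes that the pipeline measures planted
geometry correctly — not that real interactomes look like the generator.

`planted_annotations()` supplies the matching enrichment world: one
designated set hits a chosen zone at elevated density against a uniform
background, degenerating to an exact null when densities are equal. Empty
sets are disallowed, so a set that draws no member receives one uniform
node.

## Numerical and determinism choices

- All orderings are lexicographic in node identifiers (opaque,
  case-sensitive strings); component labels order by size then smallest
  contained node. Outputs are byte-reproducible run to run.
- Hypergeometric tails come from `phyper`; the test suite checks them
  against exhaustive term enumeration to 1e-12 for universes up to 60.
- Pipeline outputs are TSV with `#` header comments (package version,
  configuration hash, seed) plus JSON twins, so runs are diff-able and
  attributable.

## Known limitations

- Exact all-source BFS is O(n·m): fine at the 10^4-node scale this analysis
  targets (seconds), but not meant for 10^6-node graphs.
- Eccentricity-based centres ignore edge weights by design; confidence-
  weighted analyses need a different distance model.
- The enrichment module is deliberately flat: no ontology-DAG propagation
  or pathway-hierarchy handling, so results on hierarchical annotation
  collections count each set independently.
- The R-MAT null is the only null provided; degree-preserving rewiring and
  configuration-model nulls are out of scope.
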