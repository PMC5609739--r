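---
title: "Predicting protein complexes by mining overlapping dense subgraphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein complexes by mining overlapping dense subgraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dapgminer)
```

## The problem

Protein complexes are groups of proteins that physically associate to
perform a function. Given a protein–protein interaction (PPI) network —
vertices are proteins, edges are experimentally supported interactions,
optionally weighted by confidence — we want to recover the complexes as
dense regions of the graph. Two features of the biology shape the
method: complexes **overlap** (multifunctional proteins belong to
several complexes), and real interactomes are noisy, so a useful miner
must tolerate a few missing or spurious edges. Classical partitioning
clusterers cannot place a protein in two complexes at once;
`dapgminer` is built around subgraph *mining*, where every vertex may
seed its own candidate and candidates are free to share vertices.

## Model: dense subgraphs over a prefix DAG

A *dense subgraph* (DSG) is a pair of vertex sets $(S, C)$ such that
every pair $(s, c) \in S \times C$ with $s \neq c$ is an edge. Cliques
are the special case $S = C$, bicliques the case $S \cap C =
\emptyset$; the predicted complex is always the union $S \cup C$.

Mining works on a derived structure rather than the raw graph. Each
vertex $v$ gets a **closed** adjacency list — its neighbors *plus $v$
itself* — sorted under one global total order $\varphi$ shared by all
lists. The *directed acyclic prefix graph* (DAPG) has a node for every
value appearing in some list and an arc for every pair of consecutive
entries of some list. Because every list is sorted under the same total
order, all arcs point "forward" in $\varphi$ and the structure is
guaranteed acyclic; `build_dapg()` still verifies this with a
topological sort and refuses inconsistent input. For a node $u$,
$\mathrm{vertexSet}(u)$ is the set of vertices whose lists contain $u$;
with closed lists this is exactly the closed neighborhood of $u$, which
is what makes the algebra below work: for any set $R$ of nodes, the
pair $\left(\bigcap_{u \in R} \mathrm{vertexSet}(u),\; R\right)$ is a
valid DSG, and on a clique $K$ the intersection reaches all of $K$
(open lists would lose the seed vertex itself and cap the objective one
short).

Two sortings are supported. `ID` sorts lists by ascending vertex id.
`FREQUENCY` sorts by *descending* in-list frequency (ties by ascending
id), so that hub vertices — the ones shared by many lists — move to the
front and act as common prefixes. We deliberately use the descending
direction: on the worked example below, the ascending variant places
the deepest leaf of one clique at a DAPG root, its walk never starts,
and a planted 4-clique is lost.

## The greedy walk

Each DAPG node $u$ seeds one candidate: $S = \mathrm{vertexSet}(u)$,
$C = \{u\}$. The walk then climbs from $u$ toward a root, one parent at
a time, chosen by the *inverse traveler* function:

* `deepest` — the parent whose longest root path (`maxDepth`) is one
  less than the current node's, i.e. the parent on a deepest path;
* `sharing` — the parent whose own vertex set overlaps the current
  $S$ the most.

Both break ties toward the smallest node id, which keeps runs
deterministic. At each visited node $p$ the candidate $(S \cap
\mathrm{vertexSet}(p),\ C \cup \{p\})$ is evaluated; the step is
**accepted** only if the new $S$ is nonempty and the objective strictly
improves. A rejected node does not stop the walk — the climb continues
from $p$ regardless, so a single off-path node cannot hide a good
region closer to the root.

Objectives (`objective_score()`):

* `UNONE` — $|S \cap C|$, the unweighted objective; on a clique it
  equals the clique size.
* `WDEGREE` / `WEDGE` — total weight of the $S \times C$ edges
  normalized by $|S \cup C|$ (average weighted degree) or by
  $\binom{|S \cup C|}{2}$ (weighted edge density).
* `FWDEGREE` / `FWEDGE` — the same normalizations over *all* edges
  induced by $S \cup C$, not only the bipartite ones. Degenerate
  denominators score 0.

After every node has been mined, two cleanups run. First, candidates
whose walk accepted no step and whose seed set is larger than a single
vertex are discarded. These are "unexpanded stars": the seed state of a
hub $u$ is its whole neighborhood with $C = \{u\}$, which is a valid
but uninformative DSG, and under the FREQUENCY sorting a hub adjacent
to two distinct cliques would otherwise swallow both of them at the
maximality step. Isolated vertices (singleton seed sets) are kept, so
an edgeless graph still reports one singleton DSG per vertex. Second,
`filter_maximal()` removes any DSG whose union $S \cup C$ is contained
in another's, keeping, among identical unions, the best-scoring
candidate (ties to the smallest seed id). The survivors form an
antichain under union inclusion.

## Worked example

The bundled seven-protein fixture is the union of three cliques
$\{1,2,3\}$, $\{3,4,5,6\}$, $\{4,5,6,7\}$ — note the overlaps at
protein 3 and at $\{4,5,6\}$:

```{r}
fx <- fig1_fixture()
fx$network

cfg <- predict_config(min_size = 3, grouping = "NONE",
                      mining = mining_config("deepest", "UNONE", "ID"))
pred <- predict_complexes(fx$network, cfg)
pred$complexes
```

All three overlapping cliques are recovered, under both adjacency
sortings:

```{r}
cfg_f <- predict_config(mining = mining_config("deepest", "UNONE",
                                               "FREQUENCY"))
predict_complexes(fx$network, cfg_f)$complexes
```

To see the machinery, trace the walk seeded at protein 7 by hand. Under
`ID`, its closed list is $(4,5,6,7)$, the DAPG is a single chain $1 \to
2 \to \cdots \to 7$, and the climb from 7 intersects vertex sets
$\mathrm{vertexSet}(7) = \{4,5,6,7\}$ with those of 6, 5, 4 — each step
keeps $S = \{4,5,6,7\}$ and grows $|S \cap C|$, so all three steps are
accepted — and then hits 3, where the intersection would shrink; the
step is rejected and the best state $(S = C = \{4,5,6,7\})$, a
4-clique, is returned.

## Prediction, grouping and parameters

`predict_complexes()` wires the stages together: an optional vertex
re-ordering (`build_node_ordering()`: input order, lexicographic,
degree, random, BFS or DFS from the largest hub), the DAPG build, the
mining pass, then conversion of unions back to protein names with a
minimum size filter (`min_size`, default 3 — dimers carry too little
evidence under a density objective). With `grouping = "UNION"`,
predictions whose pairwise overlap score exceeds 0.8 are merged by
connected components into single unions, a coarsening useful when
near-duplicate candidates survive maximality on noisy weighted graphs.
The defaults (`deepest`, `UNONE`, `ID`, `min_size = 3`, no grouping)
are the configuration every acceptance property in the test suite is
pinned to.

## Evaluation

The overlap score between a predicted complex $p$ and a reference $r$
is $\mathrm{OS}(p, r) = |p \cap r|^2 / (|p| \cdot |r|)$, reaching 1
only on identical sets. On top of it:

* **FMeasure** — a prediction is a true positive when its best OS
  against any reference is at least $w$ (default 0.25, the customary
  benchmark threshold; equality counts as a match); precision, recall
  and their harmonic mean follow.
* **Sn / PPV / Acc** — from the reference-by-prediction intersection
  matrix $T$: sensitivity sums row maxima over reference sizes, PPV
  sums column maxima over $\sum T$ (so predictions overlapping nothing
  do not dilute it), and accuracy is their geometric mean.
* **MMR** — the total weight of the maximum-weight one-to-one matching
  between predictions and references (edges require OS ≥ 0.2), divided
  by the number of references. The matching is solved exactly with
  `igraph::max_bipartite_match()`, and the test suite checks it against
  an exhaustive assignment search on small instances.
* `filter_reference()` — before evaluation against a specific network,
  references with fewer than half their members present are dropped,
  the rest truncated to present members, and complexes left with fewer
  than two members removed.
* `overlap_histogram()` — cumulative counts of matched pairs above a
  grid of OS thresholds, for comparing methods beyond a single number.

## Synthetic benchmarks

`planted_network()` builds seeded ground-truth instances: cliques of
sizes drawn from `size_range` planted sequentially, each sharing one
protein with its predecessor with probability `overlap_fraction`;
optional background vertices with Erdős–Rényi noise edges; optional
uniform weight noise (which switches the network to weighted); and
optionally one dropped internal edge per larger complex to mimic
near-clique complexes. `add_random_edges()` injects a fixed fraction of
spurious interactions for robustness experiments. The generator is
deliberately simple — real interactomes have heavier-tailed degrees and
correlated noise — but it provides exact planted truth, which the
property tests exploit: noise-free planted cliques must come back with
OS = 1 each, and MMR against the truth must move by less than 0.15 on
average when 5–10 % random edges are added. The complexity suite runs
the full pipeline on networks of roughly 100 to 2000 vertices and
asserts only a monotone growth of wall-clock time, matching the
near-linear analysis of the mining pass (each node is mined once and a
walk is bounded by the DAPG height).

## False-positive screening

Predictions that match no gold-standard complex are not necessarily
wrong — catalogs are incomplete. The `fp_screen` functions implement an
offline version of a structural corroboration screen:
`false_positives()` selects the unmatched predictions,
`read_chain_map()` loads a local SIFTS-style protein→PDB-chain
snapshot, and `potential_complexes()` groups the members of each false
positive by shared PDB entry. Groups of at least two proteins that are
not a subset of any known complex are reported, with counts shown as
`k/total` where `total` is the number of distinct proteins the snapshot
maps to that PDB entry — an offline proxy for the entry's full
composition. `write_potential_complexes()` renders the CSV report,
optionally joined with a local PDB metadata table.

## Limitations

The miner is a greedy heuristic: one walk per node, strict-improvement
acceptance, no backtracking. It recovers planted cliques exactly but
carries no optimality guarantee on arbitrary graphs, and its output
depends on the chosen total order — that is by design (the order is a
tunable), but it means results should be reported together with the
ordering, traveler and objective used. The unexpanded-star pruning
removes hub neighborhoods that no walk confirmed; on graphs where a
star *is* the right answer (e.g. a true hub-spoke complex with no
triangle support) such candidates are lost. Weighted objectives assume
weights in $[0, 1]$ interpretable as interaction confidence.
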