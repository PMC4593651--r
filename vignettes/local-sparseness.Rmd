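---
title: "Local sparseness of attributed networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local sparseness of attributed networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starval)
library(igraph)
```

## The question the toolkit answers

Most topological analyses of connectomes concentrate on dense structure:
cores, communities, rich clubs. **starval** looks at the opposite end — how
*sparse* the immediate neighbourhood of each vertex is, and therefore how
much 2-hop communication that vertex must mediate for its neighbours. The
local subnetwork of a vertex (the *hub*) is the graph induced by the hub
and its adjacent vertices (the *spokes*). Two extremes anchor the scale: a
*star* (no spoke–spoke edges, the hub relays everything) and a *clique*
(every spoke pair connected directly, the hub relays nothing).

### Star value, undirected

For a hub with spoke set $C$ and $m$ edges among the spokes, the
communication workload is the number of non-adjacent spoke pairs,

$$L = \binom{|C|}{2} - m,$$

and the star value normalizes it as

$$\mathrm{SV} = \frac{2L}{|C|^2} = 1 - \frac{2m + |C|}{|C|^2}.$$

A clique hub scores exactly 0; a star hub with $k$ spokes scores
$1 - 1/k$, approaching 1 as the star grows. The modelling assumptions are
deliberately minimal: communication follows shortest hop paths, and a hub
treats itself as the relay for each of its open spoke pairs even when
parallel 2-hop routes exist elsewhere — the viewpoint is hub-centric, not
global. A useful identity (used as an independent test route) is
$\mathrm{SV} = (1 - 1/k)(1 - C_{\mathrm{local}})$, where $C_{\mathrm{local}}$
is the local clustering coefficient: the star value is a size-aware
complement of clustering, which is precisely why it distinguishes a large
star from a small one while clustering alone cannot.

### Star value, directed

In a digraph the spokes split into in-only sources $S$, out-only targets
$T$, and reciprocal neighbours $C$; traffic flows from $S \cup C$ through
the hub to $T \cup C$. The workload is

$$L = |S|(|T| + |C|) + |C|\Big(|T| + \tfrac{|C|-1}{2}\Big) - m,$$

where $m$ counts spoke-to-spoke arcs that bypass the hub. Two numerical
choices deserve explanation:

* **Half-weight for reciprocal-pair arcs.** An arc between two members of
  $C$ contributes $\tfrac12$ to $m$, so a fully reciprocal $C$-pair
  contributes exactly the single unordered unit that the
  $\binom{|C|}{2}$-type term counts. Counting such arcs at full weight
  would drive $L$ negative on reciprocal cliques and break the exact
  agreement with the undirected formula on symmetrized graphs; with the
  half-weight, $L \ge 0$ always, a clique scores 0, and a digraph whose
  arcs are all reciprocal reproduces the undirected star value vertex by
  vertex. All other source-to-target arcs ($s \to t$, $s \to c$,
  $c \to t$) count 1, and arcs in the non-communicating direction (e.g.
  $t \to s$) are ignored.

* **The denominator convention `"P1"`.** The directed normalizer is

  $$D = \frac{|S|(|T| + |C| + 2)}{2} + |T|(|C| + 1) + \frac{|C|^2}{2},$$

  the unique reading of the intended normalization that collapses to the
  undirected $|C|^2/2$ when $S = T = \emptyset$. It is *not* an upper
  bound on $L$ for every neighbourhood shape: when reciprocity is low and
  $|S|, |T|$ are large, $L/D$ exceeds 1 — on a synthetic low-reciprocity
  random digraph, most vertices do. Values are therefore reported raw and
  clipped into the end bins only when histograms are built (with the
  clipped count logged). The convention is an explicit argument (`denom`)
  so alternative normalizations can be slotted in and compared; this is a
  known limitation, not an accident of implementation.

Vertices for which the quantity is undefined (isolated vertices; directed
vertices with an empty neighbourhood partition) are excluded from
histograms and means, with counts reported.

### Attribute analyses

When each vertex carries a group code $1..K$ (for a connectome, its
super-area: a lobe, basal ganglia, diencephalon, insula or cingulate
gyrus), three attribute-aware summaries are built on top of the star
value. These analyses are defined on the undirected network; directed
input to `run_full_analysis()` is symmetrized first for them.

* **Disparity** of a hub is the number of distinct spoke codes different
  from the hub's own — 0 for a homogeneous neighbourhood, at most $K-1$.
  `disparity_profile()` reports, per disparity value, the count share,
  mean star value and mean hub degree.
* **Workload closure.** Two same-group vertices are an *open pair* if they
  are non-adjacent and share at least one common neighbour — of any group
  (the common-hub requirement makes them spokes at all; only *closure*
  asks for an in-group hub). The workload closure coefficient of a group
  is the fraction of its open pairs that have at least one same-group
  hub. A group with no open pairs is vacuously closed: the ratio is 0/0,
  and the toolkit reports `wcc = 1` together with a `degenerate` flag
  rather than an arbitrary 0. The per-group table also carries intra-group
  density and the mean local clustering of the induced subgraph, the two
  quantities that determine how much workload exists in the first place.
* **Brokerage.** On the directed network, every open two-path
  $s \to b \to t$ (direct arc $s \to t$ absent; $s \ne t$) makes $b$ a
  broker for $(s, t)$, and the triple of group codes assigns one of the
  five Gould–Fernandez roles: coordinator, gatekeeper, representative,
  consultant, liaison. Counts are unnormalized — every broker of a pair
  earns full credit however many co-brokers exist — and only the absence
  of $s \to t$ matters: a reverse arc $t \to s$ does not disqualify the
  triple (directional non-adjacency, the convention of the classical
  census). The census reports top-$k$ vertices per role and one
  best-broker matrix per role. Because the classical census tables do not
  fix a matrix orientation, the package adopts one and records it in an
  attribute and in output headers: rows index the source's group
  throughout; columns index the broker/target group for gatekeeper, the
  target group for representative and liaison, and the spokes' own group
  on the diagonal for coordinator and consultant. All ties — top lists and
  matrix cells alike — break lexicographically by vertex name, so outputs
  are reproducible.

### Null models

Three nulls isolate which structure matters:

* `iso_null()` permutes vertex labels uniformly: the topology is exactly
  isomorphic (every structural invariant, including the star-value
  multiset, is preserved bit for bit) while the attribute–topology pairing
  is randomized.
* `ms_rewire()` randomizes wiring by double-edge swaps
  $(a,b),(c,d) \to (a,d),(c,b)$, rejecting self-loops and duplicates:
  degrees (in/out separately on digraphs) and edge count are exact
  invariants, block structure is not.
* `bms_rewire()` confines swaps to edges of the same block (the unordered
  pair of endpoint groups; the ordered pair on digraphs) and keeps each
  endpoint on its own side for inter-group blocks, so the per-block edge
  count matrix and each vertex's per-block degree are additionally exact
  invariants.

The swap engine targets 10 successful swaps per edge by default — common
practice for degree-preserving randomization; the quantity is a
`rewire_config()` field, not hard-coded — with an attempt cap of 100
attempts per edge. Hitting the cap produces a warning with the achieved
count rather than silent under-mixing; the extreme case is a star, whose
degree sequence admits no other simple graph, and which is returned
unchanged. Every stochastic function takes an explicit seed, and
`null_ensemble()` derives replicate seeds as `seed + 0 .. reps - 1`, so
ensembles are reproducible and extensible. No claim of exactly-uniform
sampling over the degree-sequence ensemble is made; the swap chain is the
standard approximation.

### Generators and fixtures

`generate_er()`, `generate_ba()` and `generate_ws()` wrap igraph's
generators with seeds and deterministic vertex names. The benchmark
operating point `macaque_er_spec()` is $n = 351$,
$p = 10194/(351 \cdot 350)$. The arc number 10194 is the *symmetric-arc*
count of the undirected 351-area macaque network (each undirected edge
counted once per direction, i.e. 5097 unordered edges); calibrating ER
density with the symmetric-arc convention is the choice that makes the
expected ER clustering coefficient equal the published 0.083, whereas
treating 10194 as unordered edges would double it. For the same reason
every summary table reports both `n_edges_unique` and `n_edges_arcs` side
by side. Watts–Strogatz and Barabási–Albert settings matching that edge
budget (`neighbors = 15`, i.e. lattice degree 30; `edges_per_step = 15`)
are approximations — the exact historical parameterizations behind the
published comparison rows are not recoverable — and are treated as
demonstration outputs, not benchmarks.

Two synthetic fixtures make the test suite self-contained:
`planted_neighborhood(k, m)` builds a hub with known star value
$1 - (2m + k)/k^2$ by construction, and `attributed_block_graph()` draws
an ER-style graph with group-dependent densities, emulating the one
property of a parcellated connectome these methods depend on — dense
within-group wiring against sparser between-group wiring, with planted
star/clique neighbourhoods available through the density dials. What the
fixtures do *not* emulate is just as important: no spatial embedding or
wire-length cost, no hierarchy within groups, no reciprocity structure
beyond what independent arcs produce, and no degree heterogeneity beyond
binomial fluctuation. Passing tests therefore validate the *computations*
on block-structured inputs, not any biological claim about real
connectomes; the published macaque benchmark values themselves require the
externally curated network file, which is not bundled, and are not
asserted by the test suite.

### Histograms and moments

Star-value distributions use 20 equal bins on $[0, 1]$ by default —
half-open $[lo, hi)$ with the last bin closed at 1 — and normalized counts.
Ensemble histograms average normalized counts across realizations at fixed
bins. Skewness and excess kurtosis use population moments
($\mathrm{mean}(z^3)$ and $\mathrm{mean}(z^4) - 3$); because published
histogram-shape statistics depend on an unstated bin count, they are
treated as descriptive output here, not as benchmarks. `moment_stats()`
accepts either raw values or a binned distribution (midpoints weighted by
counts).

### Determinism and degenerate inputs

Vertex identifiers are opaque strings; every table is sorted
lexicographically and every tie broken lexicographically, so identical
invocations produce byte-identical CSVs (report headers carry the
configuration and seed, never a timestamp). Self-loops and duplicate edge
rows are dropped/collapsed with logged counts on read. Degenerate cases
follow one rule — *undefined, not zero*: workload and star value error on
isolated vertices in single-vertex calls and return `NA` in tables;
zero-variance moment input errors; a component-mode mismatch (strong on an
undirected graph) errors rather than silently reinterpreting.

### Problem sizes used by the shipped tests

The suite validates exactness on small graphs (brute-force enumeration up
to 12 vertices, 200 seeded replicates), distributional behaviour at the
$n = 351$ ER operating point with 20 seeded realizations, and pipeline
coherence on a 351-vertex, 8-block synthetic digraph of roughly the
benchmark arc density. These sizes were chosen to make every documented
property checkable in seconds while matching the benchmark row that *is*
desk-reproducible.

## A worked example

```{r example, eval = FALSE}
bg <- attributed_block_graph(c(20, 20, 20), p_intra = 0.4, p_inter = 0.05,
                             directed = TRUE, seed = 1)
star_values(bg$net)                       # per-vertex S/T/C, workload, SV
summarize_network(bg$net)                 # one-row topology summary
und <- to_undirected(bg$net)
wcc_table(und, bg$attrs)                  # closure per group
disparity_profile(und, bg$attrs)          # SV vs attribute heterogeneity
brokerage_census(bg$net, bg$attrs, k = 5) # roles, top lists, matrices
nulls <- null_ensemble(und, "bms", attrs = bg$attrs, reps = 20, seed = 1)
autoplot(ensemble_sv_distribution(nulls))
```
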