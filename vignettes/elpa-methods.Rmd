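---
title: "Edge label propagation: model, choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge label propagation: model, choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elpa)
```

## The model

ELPA (edge label propagation) detects communities in an undirected,
unweighted simple graph by propagating labels over *edges* rather than
vertices. A link community is a set of edges; because a vertex belongs to
every community its edges belong to, link communities express overlapping
membership naturally, while the label-propagation dynamic keeps the method
fast and free of tunable resolution parameters. The pipeline has four
stages, all driven purely by topology:

1. **Initialization.** Vertices are visited hubs-first (degree descending,
   ties by the canonical vertex order). Each visited vertex with unassigned
   incident edges opens a new link community containing all of them; the
   loop stops once every edge has exactly one label. Edges around hubs tend
   to form community cores, so this covering starts from far fewer
   candidate communities (about $n/2$) than one-label-per-edge would.

2. **Stage I — the triangle rule.** An edge $(b,c)$ may adopt label $i$
   when some common neighbor $a$ carries $i$ on both legs $(a,b)$ and
   $(a,c)$: two endpoints sharing a mutual contact inside community $i$ are
   taken to be internal to $i$. With several witnesses the edge joins the
   candidate community with the most edges ("largest dimension"), ties
   resolved toward the smallest label id. Sweeps repeat until a full pass
   changes no label.

3. **Stage II — trend labels.** Stage I can overwrite all of a vertex's
   edge labels with one community even though its neighborhood still
   concentrates elsewhere. Each outer pass therefore first grants every
   vertex a *trend label*: the strict-majority label of the multiset of all
   edges incident to its neighbors, or, failing a majority, the label(s)
   carried by the most distinct neighbors (all ties kept). An edge then
   considers, besides its triangle candidates, the labels its two endpoint
   views share — excluding its own current label, so an edge cannot justify
   itself through its endpoints. Adoption and tie-breaks are as in Stage I.

4. **Node propagation and bridges.** Vertices resolve their label sets by
   a three-tier rule: the unique plurality label over their neighbors'
   label sets; failing that, the unique plurality label of their own
   incident edges; failing that, the label(s) in which the edges *between*
   their neighbors concentrate, keeping ties — the one place a vertex can
   retain several labels and become an overlapping node. Edges whose
   endpoints end up sharing no label are flagged as bridges; node
   propagation is then re-run with bridges excluded from the incident-edge
   tally until the bridge set stabilizes (capped at 10 rounds). Vertices
   keep their bridge-flagged edges' labels in the link partition; bridges
   are flagged, not removed.

On the karate-club fixture bundled with the package this produces the
documented trajectory — 15 initial link communities, 9 after Stage I, 5
after Stage II, and finally the observed two-faction split:

```{r karate}
fit <- elpa(load_fixture("karate"))
fit
```

## Update discipline and determinism

The update equations are written in terms of the previous iteration
($t-1$), i.e. *synchronously*, and only synchronous sweeps reproduce the
karate trajectory above (asynchronous in-order sweeps end Stage I with 10
communities instead of 9). Synchronous edge sweeps are therefore the
default (`sync = TRUE`), with asynchronous sweeps available for
experimentation. Synchronous label dynamics can enter a period-2 limit
cycle; the stages detect this by comparing against the state two sweeps
back and stop there, which keeps every stage idempotent (re-running a stage
on its own output returns it unchanged). Node propagation runs
asynchronously in canonical order — no printed count discriminates the two
schedules there, and the asynchronous sweep converges more robustly.

All sweeps visit edges and vertices in the canonical order (numeric when
all vertex ids parse as integers, lexicographic otherwise), and every tie
is broken by community size then smallest label id, so a run is
deterministic: the same input yields byte-identical output files.

Degenerate inputs: self-loops are rejected, duplicate edges collapse with a
warning, disconnected graphs are processed per component (labels never
cross components), an empty graph yields an empty result, and each stage
carries a sweep cap (`max_sweeps = 100`, far above observed convergence)
whose breach is flagged rather than fatal.

One boundary case worth knowing: a degree-2 vertex whose two contacts fall
in different communities and share no edge (karate vertex 10) is
undecidable by all three tiers in the first node-propagation pass and
resolves during the bridge re-check loop.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `init` | `"degree"` | seeding order of the initial edge covering; `"index"` and seeded `"random"` mirror the initialization comparison |
| `sync` | `TRUE` | synchronous edge sweeps (the written update equations) |
| `max_sweeps` | 100 | per-stage sweep cap; breach flags `converged = FALSE` |
| `recompute_trend` | `TRUE` | recompute trend labels each Stage II outer pass (the loop structure of the algorithm); `FALSE` computes them once per stage |

The method itself is parameter-free in the sense that none of these change
the model — they select schedules whose default reproduces the documented
behavior.

## Evaluation metrics

* `nmi_disjoint`: confusion-matrix NMI normalized by the arithmetic mean of
  the partition entropies. The arithmetic-mean convention is chosen because
  it is the common one in community-detection benchmarking and matches the
  igraph implementation used as the independent oracle in the tests.
* `nmi_overlapping`: the cover extension built from per-vertex binary
  membership indicators and best-match conditional entropies (with the
  usual validity constraint). It equals 1 exactly on identical covers and
  is the measure used for overlapping benchmarks.
* `modularity_gn` / `modularity_overlapping`: Girvan–Newman modularity and
  its belonging-coefficient extension, $a_{vc} = 1/|M(v)|$, with
  $Q = \sum_c [W_c/m - (D_c/2m)^2]$, $W_c$ the belonging-weighted intra
  edge count and $D_c$ the belonging-weighted degree sum. The exact
  functional form of the overlap modularity used in the original evaluation
  is not reprinted in the literature we reimplement from; this variant is a
  documented stand-in chosen for one property the tests enforce to 1e-12:
  it reduces exactly to Girvan–Newman modularity on disjoint covers.
* `partition_density`: the edge-weighted mean link density of the link
  communities; 1 when every community is a spanning clique, 0 when every
  community is a tree, two-vertex communities contribute 0.

## Synthetic benchmarks

`generate_gn()` is the classic planted partition: 128 vertices in four
groups of 32 with expected degree 16, with $p_{in}, p_{out}$ solved from
the expected degree and the mixing fraction $\mu$ (the expected fraction of
a vertex's edges leaving its group). Sampling is exact per block
(binomial edge count, then a uniform subset of the pair space), so realized
mean degree is calibrated; the tests check it to within 5%.

`generate_lfr_like()` reproduces the *statistical* structure of LFR
benchmarks: truncated power-law degrees (exponent $\tau_1 = 2$, cap 50,
lower cut-off solved so the mean hits `avg_degree`), power-law community
sizes ($\tau_2 = 1$, bounds 5–50), `on` overlapping vertices with `om`
memberships, per-vertex intra/inter stub split by $\mu$. Exponent defaults
follow standard LFR conventions since no exponents are printed in the
setups we mirror; `avg_degree` defaults to 10, the denser of the two values
(5 and 10) those setups use. Three construction choices matter:

* membership assignment is random-order with a kick-out repair, and a
  vertex may only join communities larger than its per-membership intra
  degree — without this, hubs concentrate in the largest communities and
  the planted intra subgraphs become infeasible;
* each community's intra subgraph realizes its members' intra degrees
  *exactly* via Havel–Hakimi construction randomized by degree-preserving
  double-edge swaps (planted communities here are small and often dense,
  where configuration-model matching loses a large fraction of stubs to
  collisions and distorts $\mu$ badly);
* inter stubs are matched globally with rejection of pairs inside a shared
  community.

The generator is not byte-compatible with the official LFR binary (whose
internal rewiring schedule is unspecified); tests therefore assert
statistical properties — realized mixing within 0.03 of the target, size
bounds, degree caps, planted overlap counts — rather than graph identity.
What a green recovery test establishes is that ELPA reconstructs planted
covers at low mixing ($\mu = 0.1$, cover NMI well above the asserted 0.9 /
0.7 floors); it does not establish performance on real networks' degree
correlations, clustering, or core–periphery structure, which no planted
model reproduces.

## Known limitations

* Weighted, directed, dynamic and hierarchical graphs are out of scope.
* The two reference networks whose community counts the package documents
  (dolphins, college football) are not bundled; `fixture_urls()` prints
  their canonical sources, and the corresponding acceptance test stays red
  until they are fetched.
* On forests, Stage I is provably the identity (no triangles); Stage II,
  however, can merge the star covering through trend labels (on a 4-path
  the leaf edge adopts the neighboring community), so only the Stage I
  identity is asserted as an invariant.
* Synchronous sweeps stop on period-2 cycles; the state kept is the one the
  cycle re-enters, which is reproducible but is one of two equally valid
  labelings.
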