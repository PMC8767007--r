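---
title: "Cross-condition key-gene nomination: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-condition key-gene nomination: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivinet)
```

## The problem

Two comorbid diseases — the motivating case is cardiovascular and
chronic kidney disease, whose molecular relationship is poorly mapped —
are each profiled by several independent expression series. Genes
differentially expressed *in the same direction in both conditions* are
candidate shared mechanisms ("seed genes"). Projected onto a gene–gene
interaction network, their neighbourhood structure (dense modules,
influential partners) suggests which genes to prioritize for validation.
`ivinet` implements this workflow end to end, with a synthetic generator
providing ground truth for every stage.

## DEG filtering and overlap

Each per-series record carries a gene symbol, log2 fold change and
p-value. A gene is *up* in a series when `pvalue < p_max` and
`lfc_low <= logFC <= lfc_high`, *down* symmetrically; defaults
`p_max = 0.05`, band `[0.5, 2]`.

Conventions worth making explicit:

* **Strict p cut, closed fold-change band.** The p comparison is
  strict (`<`), the band inclusive at both ends. The *upper* bound is
  unusual — most screens only impose a lower one — but is enforced as
  configured; `lfc_high = Inf` disables it. A band has the practical
  effect of excluding extreme, often artifact-driven fold changes on
  mixed-platform panels.
* **Raw p-values.** Multi-platform panels with tiny sample sizes can
  lose every gene to multiplicity adjustment; screening here uses raw
  p with the fold-change band as the primary index. This is a screening
  choice, not an inference claim.
* **Per-series thresholds.** Different platforms justify different
  windows, so `build_condition_sets()` accepts per-series overrides of
  all three thresholds.
* **Probe collapse.** Duplicated (gene, series) records — multiple
  probes per gene — collapse to the record of maximal `|logFC|`, after
  uppercasing symbols.

Per-condition unions of the per-series up/down sets are intersected
across conditions. A gene landing in *both* the up- and down-overlap
(possible via different series) is moved to a `discordant` set rather
than silently dropped, so the up- and down-overlaps stay disjoint and
their sizes add up to the total. Union totals are reported separately in
the Venn summary; they are bookkeeping, not intersections.

## Component centralities

All seven are implemented directly on the package's adjacency-list
container (igraph is used only for GraphML serialization, and as an
independent oracle in the test-suite — never on the analysis path).

* **Degree** `dc(i)`: neighbour count.
* **Betweenness** `bc(i)`: unnormalized, endpoints excluded, each
  unordered pair counted once, geodesic-count weighted (Brandes'
  algorithm). Disconnected pairs contribute nothing.
* **Neighborhood connectivity** `nc(i)`: mean neighbour degree;
  0 for isolated nodes.
* **H-index** `h(i)`: largest h with ≥ h neighbours of degree ≥ h.
* **Local H-index.** The field's prose definitions are ambiguous between
  two readings. The default, `lh(i) = h(i) + Σ_{j∈N(i)} h(j)`, is the
  established closed-neighbourhood sum, which propagates second-order
  information; an H-index computed over the neighbours' H-indices is
  available via `score_config(lh_mode = "second_order")`, with no claim
  that either exactly reproduces any particular published table.
* **ClusterRank** `cr(i) = base^(-c_i) · Σ_{j∈N(i)} (dc(j)+1)`, with
  `c_i` the local clustering coefficient (0 for degree < 2, avoiding
  0/0) and penalty base 10 from the method's source literature — the
  base is configurable because it is a convention, not a measurement.
* **Collective influence**
  `ci(i) = (dc(i)−1) · Σ_{dist(i,j)=d} (dc(j)−1)` over the frontier at
  *exactly* distance d (literal reading of "at a distance d"), default
  `d = 3` — the convention of the influence-analysis tooling this score
  comes from. With d above the graph diameter the score is 0 everywhere.

## The IVI combination

The combination operators are centralized in one place
(`spreading_score()`, `hubness_score()`, `ivi()`) because published
descriptions name the ingredients but not always the algebra; the
architecture implemented is that of the published IVI tool:

1. each component is range-normalized onto [1, 100] (primed);
2. `spreading_raw = (nc′ + cr′)(bc′ + ci′)`,
   `hubness_raw = dc′ + lh′`;
3. `ivi_raw = hubness · spreading` (of the normalized versions), then a
   final range normalization.

The lower normalization bound is 1, not 0, so a multiplicative
combination never annihilates a node — consistent with published score
tables whose minima are exactly 1. Consequences tested as properties:
the argmax of every non-constant column scores exactly 100; constant
columns collapse to 1 (so a vertex-transitive graph scores 1
everywhere); multiplying any raw component by a positive constant
changes no rank (normalization absorbs scale); all scores are
label-invariant.

## MCODE and the module hierarchy

The three canonical stages, with the standard parameter values (degree
cutoff 2, node score cutoff 0.2, k-core 2, max depth 100):

1. **Vertex weighting**: weight(v) = k_max · density of the highest
   k-core of the closed neighbourhood G[N(v)∪{v}]; 0 when the
   neighbourhood has no 2-core or deg(v) < degree cutoff.
2. **Complex prediction**: highest-weight unassigned node seeds a
   breadth-first traversal including unassigned neighbours with weight
   > seed_weight · (1 − node score cutoff), to at most max-depth hops;
   complexes are node-disjoint. Seed ties break lexicographically by
   symbol, and complexes are ordered by MCODE score
   (density × node count, so a clique K_n scores n) with the first
   member symbol as tie-break — determinism is a contract, tested
   byte-wise.
3. **Post-processing**: complexes without a 2-core are dropped;
   haircut (default on) iteratively strips members of induced degree
   < 2; fluff (default off) may add dense boundary neighbours. Whether
   any given published analysis ran haircut/fluff is usually unstated;
   the defaults here are the common tool defaults and both are
   configurable.

`decompose_hierarchy()` recurses into each module's induced subgraph
until modules are triangle motifs (3 nodes, 3 edges) or reproduce
themselves — a clique yields itself, so it becomes a leaf rather than
recursing forever. Modules under 3 nodes are excluded from reports.
Seed-gene annotation intersects module members with the overlap genes
and reports per-module counts plus the seeds *not retained* by the
network (absent from it) — an expected outcome, since interaction
databases never house every DEG.

## Hamiltonian Energy

`HE = E_c − γ·N_c` with γ = 0.8 by default. It is linear in (N, E); for
cliques it reduces to `n(n−1)/2 − 0.8n`, strictly increasing in n, so in
hierarchies whose levels shrink module sizes the profile declines with
depth. That decline is an *empirical observation*, not a theorem, so
`level_energy_profile()` reports a monotonicity diagnostic (fraction of
child modules below their parent's HE) rather than enforcing it. No
published numeric HE values exist to compare against; the closed forms
above are what the tests pin down.

## The synthetic world

`gen_deg_series()` plants `n_shared_up` + `n_shared_down` genes that
pass the default filter with concordant sign in *every* series of both
conditions: signal p-values uniform on (1e-6, `p_signal = 0.01`), null
p-values uniform on (0.05, 1) — a deliberately unambiguous separation —
and signal fold changes uniform in the band. The remaining genes are
decoys split 40/30/30 between the three rejection paths (fail p
everywhere; significant p but fold change outside the band everywhere;
fully significant but in one condition only), so every branch of the
filter and of the intersection logic is exercised. Defaults (6 + 5
series, 19 + 24 planted among 2500 genes) mirror a realistic
cardio-renal panel.

`gen_ppin()` grows a preferential-attachment backbone (attach 2 edges
per node, the standard choice giving a scale-free degree tail) and wires
in each planted clique through a dedicated degree-2 connector. The
connector's neighbourhood is a path with no 2-core, so its MCODE weight
is 0 and traversal cannot cross the bridge — this is what makes planted
cliques exactly recoverable (Jaccard 1.0 in the tests).

What the generator does **not** emulate: probe-level intensities,
limma-style model fitting, batch effects, correlated noise between
series, degree-dependent false interactions, or realistic p-value
distributions near the threshold. A green recovery test therefore
establishes that the set algebra and module detection are correct under
clean separation — not that the thresholds are well-calibrated for real
microarray noise.

One interaction deserves emphasis: single-bridge attachment makes
planted cliques *globally peripheral*. Their members dominate
degree-matched backbone nodes on **hubness** (roughly twofold — the
property the test-suite asserts across seeds) but not on spreading or on
the spreading-weighted IVI, because a bridge of one edge concentrates
betweenness and collective influence on the backbone, not the clique.
With a connector per clique member (denser attachment) IVI dominance
would return, but module recovery would no longer be exact; the
generator keeps the separable design and the documentation keeps this
caveat.

## Numerical and interface choices

* All tables and serializations are sorted (nodes lexicographically,
  edges by endpoints) and written with fixed decimal formats, so
  identical config + seed means byte-identical bundles; the pipeline
  manifest records every effective parameter and suffices to reproduce
  a bundle.
* Configuration files are JSON (`jsonlite`), chosen over a YAML dialect
  to avoid a dependency not guaranteed in minimal installations; the
  schema is the nested list printed by `default_config()`.
* Betweenness correctness is established by a dual route: exhaustive
  geodesic enumeration (Floyd–Warshall distances + recursive path
  enumeration, sharing no code with the Brandes implementation) on all
  labeled ≤5-node graphs and sampled 6–7-node graphs, and igraph on
  random 200-node graphs to 1e-9.
* Degenerate inputs: empty record lists filter to empty sets; an
  edgeless graph yields an empty hierarchy; isolated nodes get nc = 0,
  h = 0, cr = 0; a single-node graph has density 0 by convention;
  `range_normalize()` of a constant vector returns the lower bound and
  of an empty vector errors.

## Limitations

Unweighted, undirected topology only (interaction confidence scores are
parsed and ignored); no enrichment analysis, no miRNA/drug layers, no
expression-matrix processing — inputs begin at DEG tables. Centralities
are exact, single-threaded R; practical up to a few thousand nodes
(Brandes is O(nm)), which covers typical DEG-derived interaction
networks but not whole interactomes.
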