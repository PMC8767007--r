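# ivinet

Nominating key genes shared between two disease conditions — for example
cardiovascular disease (CVD) and chronic kidney disease (CKD), whose
comorbidity motivates exactly this kind of cross-condition analysis — by
combining differential-expression evidence with the topology of a
gene–gene interaction network.

The package is aimed at computational biologists who have per-series DEG
tables (gene symbol, log fold change, p-value) from several expression
series per condition, plus an undirected interaction network (e.g. a
STRING export), and want a reproducible, scriptable version of the
common "overlap → network → centrality → modules" workflow.

## What it computes

1. **DEG filtering and overlap.** Each series is filtered with a strict
   p-value cut (p < 0.05) and a closed fold-change band
   (0.5 ≤ |logFC| ≤ 2, per-series overridable). Per-condition unions
   X<sub>u</sub>, X<sub>d</sub>, Y<sub>u</sub>, Y<sub>d</sub> are
   intersected across conditions:
   up-overlap = X<sub>u</sub> ∩ Y<sub>u</sub>,
   down-overlap = X<sub>d</sub> ∩ Y<sub>d</sub>; genes claimed by both
   are quarantined as *discordant*. The shared genes are the *seed
   genes* of the network analysis.

2. **Integrated Value of Influence (IVI).** Seven component centralities
   are implemented from scratch: degree (DC), betweenness (BC, Brandes),
   neighborhood connectivity (NC), H-index, local H-index (LH),
   ClusterRank (CR) and collective influence (CI). After
   range-normalizing each component onto [1, 100] (denoted ′):

   - spreading = (NC′ + CR′) · (BC′ + CI′) — capacity to disseminate
     influence;
   - hubness = DC′ + LH′ — local sovereignty;
   - IVI = normalize(hubness′ · spreading′), so the most influential
     node of any graph with non-constant scores scores exactly 100.

3. **MCODE dense-module detection.** Vertex weighting by the density of
   the highest k-core of each closed neighbourhood, seeded traversal
   above a node-score cutoff (defaults: degree cutoff 2, node score
   cutoff 0.2, k-core 2, max depth 100, haircut on), recursive
   decomposition of modules into sub-modules down to triangle motifs,
   and seed-gene tracing per module.

4. **Hamiltonian Energy.** HE = E<sub>c</sub> − γ·N<sub>c</sub>
   (γ = 0.8) per module, profiled across hierarchy levels as a
   stability/organization diagnostic.

A synthetic-data generator plants known shared genes into DEG tables and
known cliques into a scale-free network, so every stage can be verified
against ground truth.

## Worked example

```r
library(ivinet)
cfg <- default_config(seed = 11)   # synthetic cardio-renal-style panel
b   <- run_pipeline(cfg, outdir = "demo_out")
```

Stage log (printed by the run):

```
deg: 11 series loaded
overlap: 19 up + 24 down = 43 shared genes (0 discordant)
network: 500 nodes, 1012 edges, 1 component(s)
influence: top node N00001 (ivi 100.00)
modules: 5 found, 3 with seed genes; seeds retained 19 of 43 (24 not retained)
energy: 6 hierarchy rows, root HE 612.00, frac below parent 1.00
```

The default synthetic world mirrors a realistic panel: 11 series (6 + 5)
with 19 up- and 24 down-regulated shared genes planted (43 total), and a
500-node scale-free network carrying three planted cliques (8 + 6 + 5
members) that hold 19 of the 43 shared genes — so 24 seeds are "not
retained" by the network, and the three seed-bearing modules are
recovered exactly:

```r
rank_top(b$influence, 5)
#>   rank   node     score
#> 1    1 N00001 100.00000
#> 2    2 N00002  52.55830
#> 3    3 N00007  28.59857
#> 4    4 N00005  17.93473
#> 5    5 N00006   9.76509

head(b$energy_profile)
#>   level module_id nodes edges    he
#> 1     0      root   500  1012 612.0
#> 2     1         1     8    28  21.6
#> 3     1         2     6    15  10.2
#> 4     1         3     5    10   6.0
#> 5     1         4     4     5   1.8
#> 6     1         5     3     3   0.6
```

The top IVI node scores exactly 100 (the normalization pins the argmax
there); the three highest-scoring modules are the planted cliques
(MCODE scores 8, 6, 5 = clique sizes, since a clique's score
density × n equals n); and HE decreases monotonically down the
hierarchy as module sizes shrink.

Everything lands under `demo_out/` with fixed names (`influence.tsv`,
`modules.tsv`, `energy_profile.tsv`, `top_ivi.tsv`, `manifest.json`,
…). The manifest records every effective parameter; re-running with the
same config and seed reproduces the bundle byte for byte.

## Command line

```sh
inst/cli/ivinet run      --config cfg.json --outdir out
inst/cli/ivinet simulate --seed 2 --outdir sim
inst/cli/ivinet scores   --network net.tsv --outdir out
```

Subcommands: `simulate`, `overlap`, `scores`, `modules`, `energy`,
`run`, `report` (re-runs from an existing `manifest.json`).

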