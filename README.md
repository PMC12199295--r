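# rxnmc — reaction-based Monte Carlo ligand design

`rxnmc` is an R implementation of a Monte Carlo Metropolis (MCM) engine for
de novo ligand design over *combinatorial synthon libraries*: chemical
spaces defined implicitly by reaction templates (reaction SMARTS) plus
per-component reagent lists, as used by make-on-demand catalogues. Every
molecule the engine ever proposes is a product of one library reaction
applied to library synthons, so every design is synthetically accessible by
construction. It is aimed at computational chemists who want to study or
extend similarity-guided MCM sampling of ultra-large chemical spaces at
desk scale, with a pluggable scorer standing in for a docking engine.

## The method

Each Monte Carlo iteration proposes a new molecule and accepts it with the
Metropolis rule on the size-normalised ligand-efficiency score

    LE2 = E / N_HA^2        (REU per squared heavy-atom count, lower = better)

where `E` is the interface energy from the active scorer. The proposal step
ranks library fragments by the asymmetric Tversky similarity (0.1 on the
reference, 0.9 on the fragment) to the current molecule and routes them —
drawn by a *geometrically weighted rank sampler* — into reaction
containers; the products formable from the filled containers are the
candidates, one of which is drawn by the same sampler on Tanimoto rank.

The rank sampler is controlled by a single sampling ratio `x`: rank `k` of
an `n`-item list gets weight proportional to `(1-r) r^(k-1)` with
`r = x^(1/(x n))`, so the top `x` fraction of the list always carries
`1 - x` of the sampling mass (at `x = 0.1`, the top 10% carry 90%).
A dynamic controller adapts `x` during the run — up by `s` on every
rejection (to escape exhausted neighbourhoods, capped at `M`), reset to `m`
on acceptance — followed by a refinement phase at a fixed small ratio.
Optionally each proposal is placed in the binding pocket by
common-substructure atom mapping plus rigid (Kabsch) superposition of
conformers onto the previous pose, and rejected if its centre of mass
leaves the pocket sphere. A cascaded workflow reruns the engine from a
diverse selection of the best designs of the previous round.

## A worked example

```r
library(rxnmc)

lib <- make_fixture_library(3, 12, seed = 7)   # desk-scale synthetic library
lib
#> <rx_library> 3 reactions, 71 unique synthons
#>   amide: 12 x 12 synthons
#>   sulfonamide: 12 x 12 synthons
#>   diacylamine: 12 x 12 x 12 synthons

# a hidden-target surrogate scorer and a poorly scoring random start
bm <- desk_benchmark(seed = 7)
route <- run_route(bm$lib, bm$start, bm$cfg, bm$scorer, seed = 101)
summary(route)
#> Monte Carlo design route
#>   iterations:      200
#>   accepted moves:  19
#>   scored props:    200
#>   best design:     CCCNC(=O)c1sccc1OCC
#>   best score:      -0.42857
#>   mean step size:  0.9025  (Tanimoto between consecutive accepted ligands)
```

The best design is an amide of the hidden target's own thiophene acid with
a small propylamine — exactly what the LE2 score rewards: a light molecule
sharing many structural features with the target. `plot(route)` draws the
accepted-state score trace; `run_campaign()` runs the multi-round cascaded
version, and `random_baseline()` builds the equal-budget random comparison
set:

```r
base <- random_baseline(bm$lib, n_scored_unique(route), bm$scorer, bm$cfg,
                        seed = 701)
min(base$le2)        # best random molecule at the same evaluation budget
#> [1] -0.3733333
```

Diagnostics follow the method's own metrics: `mean_step_size()` (Tanimoto
between consecutive accepted ligands), `output_diversity()` (per-molecule
maximum similarity within a design set), `novelty_vs_reference()`, and
`scaffold_diversity()` (% unique Bemis–Murcko scaffolds).

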