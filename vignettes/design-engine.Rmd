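---
title: "Reaction-based Monte Carlo ligand design: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-based Monte Carlo ligand design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnmc)
```

## The design problem

Make-on-demand combinatorial libraries describe billions of purchasable
molecules implicitly: a few hundred reaction templates (as reaction SMARTS)
and lists of building blocks ("synthons") for each reaction component. Any
product of a template applied to its synthons is synthetically accessible by
construction. `rxnmc` implements a Monte Carlo Metropolis (MCM) optimizer
over such a space: starting from an arbitrary molecule, it proposes new
molecules that are always library products, scores them with a pluggable
scorer, and accepts or rejects each proposal with the Metropolis rule on a
size-normalised ligand-efficiency score

$$\mathrm{LE}_2 = \frac{E}{N_\mathrm{HA}^2},$$

where $E$ is the interface energy reported by the scorer (REU, lower =
better) and $N_\mathrm{HA}$ the heavy-atom count. The quadratic
normalisation softens the bias toward large molecules that raw interface
energies carry, and penalises tiny fragments less brutally than linear
ligand efficiency.

## One iteration

1. **Proposal.** Library fragments are ranked by Tversky similarity to the
   current molecule (weights 0.1 on the reference, 0.9 on the fragment: a
   fragment wholly contained in the reference scores near 1, making the
   index a substructure similarity). A geometrically weighted rank sampler
   draws fragments without replacement and routes each into every reaction
   component whose SMARTS template it matches. After each batch, all
   products formable from the filled containers are enumerated; the loop
   stops at `candidate_limit` candidates. Candidates are ranked by Tanimoto
   similarity to the current molecule and one is drawn with the same rank
   sampler.
2. **Filters.** A log P bandpass (penalty of +0.5 LE2 outside [0, 5],
   rejection outside [−1, 8]), a synthetic-accessibility cutoff (estimate
   > 6 rejects), and optional molecular-weight / rotatable-bond bounds run
   before any scoring.
3. **Pose (optional).** When the route tracks a 3-D pose, atoms of the
   proposal are mapped onto the current ligand via a bounded
   maximum-common-substructure search, conformers of the proposal are
   superposed rigidly (Kabsch) over the mapped atoms, the lowest-RMSD
   conformer is kept, and poses whose mass-weighted centre of mass leaves
   the binding-pocket sphere are rejected.
4. **Metropolis.** The proposal is accepted with probability
   $\min(1, e^{-\Delta \mathrm{LE}_2 / kT})$; a better score is always
   accepted.

## The geometric rank sampler

For a similarity-ranked list of $n$ items and a sampling ratio
$0 < x < 1$, rank $k$ receives the raw weight

$$a_k = (1 - r)\, r^{k-1}, \qquad r = x^{1/(x n)},$$

renormalised over the $n$ ranks. The common ratio is chosen so the top
$x\,n$ ranks carry exactly $1 - x$ of the raw mass
($1 - r^{xn} = 1 - x$): at $x = 0.1$ the top decile of the list carries
90% of the sampling weight, at $x = 0.01$ the top percentile carries 99%,
for any list size. This makes the *ranking* — not the skewed similarity
scores themselves — the basis of the bias, and the bias scale-free across
library sizes.

Numerical notes: the truncated tail mass is $x^{1/x}$ (below $10^{-10}$
for all practical $x$), but weights are always renormalised; ties in the
similarity ranking are broken by stable sort so sampling is reproducible;
for $x n < 1$ the common ratio is tiny and rank 1 is drawn essentially
deterministically — the intended "fixed small step" regime of the
refinement phase at production scale.

## Dynamic step size and the two-phase schedule

The *step size* of a route is the structural similarity between consecutive
accepted ligands. It is controlled by the sampling ratio: small $x$
proposes close analogs, large $x$ reaches further. The dynamic controller
keeps the ratio in a band $[m, M]$: each rejected iteration increases it by
$s$ (capped at $M$), each *effective* acceptance resets it to $m$. Routes
run an exploration phase with the controller on, then a refinement phase at
a fixed small ratio with the controller off. Production-scale defaults
(`run_config()`) are 2000 iterations, the controller at
$[0.01, 0.2]$ with $s = 0.002$ for the first half, then a fixed ratio of
$10^{-4}$.

**Accepted no-ops.** The current molecule is itself a library product and
its own synthons top the similarity ranking, so the engine regularly
re-proposes the current state; the proposal has $\Delta = 0$ and the
Metropolis rule accepts it. With a deterministic scorer such a no-op
changes nothing, and on a desk-scale library it would recur indefinitely if
it also reset the controller. The controller therefore treats an accepted
no-op like a rejection: the step size keeps ramping until the search
actually moves. This is the same trapped-in-a-neighbourhood escape
behaviour the dynamic schedule exists to provide, extended to the
degenerate trap of re-proposing the current state; with a noisy
production-grade scorer re-scoring breaks the tie and the distinction
vanishes.

## The Metropolis temperature

$kT$ sets how readily worse-scoring proposals are accepted, in LE2 units.
On the shipped surrogate landscape (below), design-score differences
between neighbouring library products are typically 0.003–0.1 LE2 units;
the package default $kT = 0.1$ (appropriate for raw-REU-scale scores of
docking engines) would accept almost every uphill move there. Desk-scale
runs therefore use $kT = 0.0025$, at the lower edge of the neighbour gap
scale: downhill always, near-lateral moves ($\Delta \lesssim 0.003$)
occasionally, anything clearly worse essentially never. A hotter chain
measurably diffuses on this landscape — it accepts enough lateral moves to
keep resetting the step-size controller and wanders shallow basins instead
of descending. $kT$ is a required configuration value precisely because it
must track the score scale of the active scorer.

## The surrogate scorer and the synthetic fixture library

`make_surrogate_scorer(target, scale)` scores a molecule as
$-\mathrm{scale} \cdot |fp(\mathrm{mol}) \cap fp(\mathrm{target})|$ over
path fingerprints: deterministic, smooth in structural similarity, and
minimised (over any candidate set containing it) by the hidden target. It
emulates the one property of a docking score the optimizer relies on —
neighbouring molecules have correlated scores — and none of its physics.

`make_fixture_library()` builds a deterministic desk-scale stand-in for a
make-on-demand library: amide coupling, sulfonamide formation and a
three-component double acylation (optionally Williamson ether synthesis),
each with randomised but chemically valid synthon sets (default 12 per
component, giving $\sim 10^2$ products per two-component reaction and
$\sim 1.7 \times 10^3$ for the three-component one). What it emulates:
per-reaction synthon lists, SMARTS-validated routing, overlapping fragment
families across reactions. What it does not: the size (billions vs.
thousands), the density and redundancy of real synthon space, real
reagent availability, and any binding physics. Tests passing on this
fixture therefore validate the *machinery and its statistical behaviour*,
not chemical accuracy on real targets.

## Desk-scale study conditions

The engine's behavioural claims (optimizer beats equal-budget random
sampling; step size is monotone in the sampling ratio) are exercised at
desk scale under fixed conditions chosen once:

* fixture library `make_fixture_library(3, 12)`; hidden target = the
  product of the first synthon of each component of the first reaction;
  start = the worst-scoring molecule of a 100-product random baseline
  (mirroring the production protocol of starting from a poorly docked
  random molecule);
* routes of 200 iterations, exploration for the first 150 with the
  controller at $[0.05, 0.6]$, $s = 0.04$, then refinement at a fixed
  ratio of 0.08; `candidate_limit` 60; $kT = 0.0025$;
* comparison budget: each random baseline receives as many molecules as
  the paired route *scored distinctly*. The scorer is deterministic and
  memoised, so re-encountering a molecule costs nothing; counting distinct
  scored molecules is the honest evaluation-cost currency.

The controller band differs from the production defaults deliberately: the
sampling ratio only mixes when $x \cdot n \gtrsim 1$, and with ~70 unique
fragments and ~60 candidates, the production band $[0.01, 0.2]$ spends
most of its range in the deterministic regime. The desk band keeps the
minimum step stochastic ($m \cdot n_\mathrm{cand} = 3$) and lets the cap
reach across reaction families ($M \cdot n_\mathrm{frag} \approx 42$); the
increment $s = 0.04$ takes a chain from $m$ to the cap within ~14
rejections, so a route that stalls — or wanders a shallow basin with
frequent lateral acceptances — still reaches family-crossing step sizes
well inside the exploration phase.

## Cascaded multi-round optimization

`run_campaign()` ranks finished routes by best design score, keeps the top
`top_k` (default 5), greedily selects `pick` seeds maximising the minimum
pairwise Tanimoto distance (the best route is always extended), and
launches fresh routes from each seed with scorer and filter state reset;
only the ligand (and optionally its pose) crosses rounds. Route $i$ across
the campaign uses seed $\mathrm{seed} + i$, so campaigns are reproducible
and routes independent.

## Chemistry layer: scope and numerical choices

* **Toolkit.** SMILES canonicalisation, path-based fingerprints (FP2:
  linear paths of 1–7 atoms hashed to 1024 bits), molecular-weight /
  H-bond-donor / acceptor / log P descriptors and 3-D embedding are
  delegated to OpenBabel via ChemmineOB. Fingerprint width follows the
  toolkit's native default.
* **Reaction SMARTS.** Applied by the package's own restricted engine:
  element / aromatic / charge / H-count / connectivity / ring primitives,
  logical operators, atom maps; recursive SMARTS and stereochemistry are
  unsupported and raise errors. Multi-match substrates yield the first
  sanitised product in a deterministic match order. Products are
  re-canonicalised and valence-checked; failures are soft (the combination
  is skipped).
* **Aromaticity** is perceived per ring (sizes 5–6) with a simplified
  Hückel count on the kekulised graph; exotic aromatics (azulenes,
  charged 7-rings) are treated as aliphatic. Scope-appropriate, and the
  documented limitation of the SMARTS engine.
* **Atom mapping** is a bounded backtracking search for a large connected
  common substructure (element + aromaticity + bond order). Within its
  budget (default 2×10^5 steps) it is exhaustive for drug-sized molecules;
  beyond it, the best mapping found is returned.
* **Conformers** default to a torsion-sampling provider: one embedded
  geometry, then seeded random rotations about each rotatable bond. It is
  a contract implementation — cheap, seeded, and replaceable — not a
  physical conformer ensemble.
* **Synthetic accessibility** is this package's own monotone complexity
  estimator (size, ring fusion, quaternary centres, heteroatom load,
  charges) mapped to the conventional 1–10 scale. It tracks fragment-based
  synthetic-accessibility scores in trend, not in value, and is used only
  as a rejection filter with a generous default cutoff.
* **Degenerate inputs.** Two all-zero fingerprints compare as identical
  (similarity 1); acyclic molecules share the empty scaffold; a pose
  mapping of fewer than 3 atoms falls back to translation-only alignment
  with a warning; an empty atom mapping rejects the iteration.

## Known limitations

The surrogate landscape rewards fingerprint overlap, so conclusions about
*binding* require swapping in a structure-based scorer through the scorer
contract. The desk-scale library is small enough that random sampling is a
strong competitor at matched budgets; the engine's advantage there is
real but modest, and grows with library size as blind sampling dilutes.
Pose handling is geometric only: no force field, no clash model, no
protein flexibility.
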