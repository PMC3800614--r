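---
title: "Mixed-resolution GA folding on the FCC lattice: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-resolution GA folding on the FCC lattice: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fccfold)
```

## The model

`fccfold` predicts coarse-grained protein structures ab initio on the 3D
face-centred-cubic (FCC) lattice. A structure is a *self-avoiding walk*
(SAW): residue $i$ occupies lattice point $p_i$, consecutive residues sit on
neighbouring points, and no point is used twice. Each FCC point has 12
neighbours, reached by the basis vectors

$$v_1=(1,1,0),\ v_2=(-1,-1,0),\ v_3=(-1,1,0),\ v_4=(1,-1,0),\
v_5=(0,1,1),\ v_6=(0,1,-1),$$
$$v_7=(1,0,1),\ v_8=(1,0,-1),\ v_9=(0,-1,1),\ v_{10}=(-1,0,1),\
v_{11}=(0,-1,-1),\ v_{12}=(-1,0,-1).$$

This order is frozen (`fcc_basis()`), and every "first successful move" scan
in the package walks candidates in it, with residues traversed N to C. All
geometry is exact integer arithmetic, so self-avoidance checks are bit-exact.

Two contact energy functions score a conformation. Both sum over
*contacts*: non-consecutive residue pairs $(i,j)$, $j>i+1$, one lattice bond
apart,

$$E \;=\; \sum_{i<j-1} c_{ij}\, e_{ij},$$

where $c_{ij}$ indicates a contact. The low-resolution **HP model** assigns
$e_{ij}=-1$ when both residues are hydrophobic (Gly, Ala, Pro, Val, Leu,
Ile, Met, Phe, Tyr, Trp) and 0 otherwise. The high-resolution **BM model**
takes $e_{ij}$ from the empirical Berrera et al. 20x20 contact-potential
matrix, embedded verbatim as `bm_matrix()` with a 210-entry checksum. The
matrix's large-magnitude entries are concentrated in hydrophobic pairs, so
the HP classification is a coarse but directionally informative summary of
it.

The package's central idea is to *mix the resolutions*: the search is
scored by the BM matrix, but hydrophobicity knowledge steers one operator -
a macro-mutation that squeezes hydrophobic residues towards their centroid
(the hydrophobic core centre, HCC). Four variants isolate the contributions:

* **BH** - BM search energy, HP-guided macro-mutation (the headline
  algorithm);
* **BD** - BM search energy, macro-mutation accepts diagonal moves by BM
  energy instead (no hydrophobicity knowledge);
* **BM** - no macro-mutation at all (baseline);
* **HP** - HP search energy throughout (results still reported as BM).

## Representation and duplicate detection

A `conformation` stores the sequence, integer coordinates, and the
*relative encoding*: the string of basis-vector indices along the chain.
The encoding is translation-invariant, decodes from the origin, and is the
package's duplicate key - two conformations are duplicates iff their
encodings are identical. No quotient by lattice rotations or reflections is
applied: symmetric copies count as distinct, which keeps duplicate removal
cheap and predictable. The encoding is an absolute basis-vector string
rather than a turn-based (orientation-relative) code; the absolute form
makes crossover splicing and duplicate hashing trivial, at the cost of not
identifying rotated copies - which the duplicate policy ignores anyway.

## Move operators

All operators preserve the SAW invariant or report `infeasible` leaving the
input untouched, and none alters the sequence.

* **Diagonal move** - an interior residue relocates to a free point
  adjacent to both chain neighbours (two bonded FCC points share four
  common neighbours).
* **Pull move** - residue $i$ moves to a free target adjacent to both
  itself and one chain neighbour; residues on the far side are dragged
  along the positions the chain just vacated until validity is restored.
  Ends also admit simple relocations next to the penultimate residue.
  Because dragged residues reuse only freshly vacated positions and the
  target is free, a feasible pull can never produce an invalid walk; every
  pull has an inverse pull (verified exhaustively for all chains of up to 8
  residues).
* **Tilt move** - the maximal straight run containing a chosen bond is
  translated by a basis vector orthogonal to the run direction, then both
  flanks re-attach by the same drag rule as pull moves. The published
  description ("immediately parallel lattice positions") leaves the offset
  set open; restricting offsets to single orthogonal basis vectors is the
  smallest choice that keeps the run parallel and the drag argument valid.
* **Rotation move** - the tail after a pivot is mapped by one of the nine
  proper axis rotations (90/180/270 degrees about x, y, z). The published
  operator does not name a rotation group; the nine axis rotations are the
  smallest natural point-group subset that maps the basis set to itself.
* **Single-point crossover** - children splice one parent's encoding head
  with the other's tail at a split point; each child is decoded and
  validated independently.
* **Macro-mutation** - one Bernoulli draw per call picks the traversal
  class: polar with probability $p = 0.2$, hydrophobic otherwise. Visited
  polar residues take their first feasible diagonal move; hydrophobic
  residues take the first feasible diagonal move that does not increase
  their distance to the HCC. Distances are compared as exact integers by
  scaling with the squared hydrophobic count ($|n_H p - S|^2$ where $S$ is
  the coordinate sum), avoiding floating-point ties. The HCC is refreshed
  after every accepted relocation so the acceptance test tracks the moving
  core; the draw-once (rather than per-residue) Bernoulli keeps one call
  one coherent sweep. The traversal repeats `repeats = 3` times per call -
  enough for visible core contraction while keeping a single call cheap.

## The search loop

Each generation draws one operator uniformly and uses it for the whole
generation. Mutation operators are applied *exhaustively*: sites are
scanned in frozen order and the first strictly improving result replaces
the parent, otherwise the parent survives - so the population's best energy
never worsens. Crossover generations repeatedly draw random parent pairs,
generate children at every split point, and keep the best two of parents
plus children; the incumbent best member is always carried over. Duplicates
are never inserted.

When the best energy stalls for `stagnation_window = 20` generations
(the published account leaves the window open; 20 generations is long
enough to distinguish a stall from normal operator variance at these
population sizes), every member takes a *random walk* of pull moves, bounded
by $50 n$ pulls. The walk tracks the relative energy change $|\Delta E /
E_0|$ and the diversity $D$ (fraction of differing encoding positions) and
returns the visited state of maximal $D$ subject to $|\Delta E/E_0| \in
[0.05, 0.10]$ and $D \in [0.10, 0.75]$ - close in energy, far in structure.
The published description states the two bands but not the acceptance rule;
maximising diversity subject to both bands is the reading that makes the
walk a pure diversifier. With $E_0 = 0$ the relative band is undefined and
the input is returned. Population size defaults to 100 (unstated in the
published protocol; a conventional GA scale), configurable throughout.

Initialisation grows random SAWs (uniform free-neighbour choice, restart on
dead ends); after `init_max_tries` failures a deterministic extended
zig-zag is substituted, with a kink at increasing positions for later
members so the population stays duplicate-free.

All randomness flows through R's RNG seeded once per run: identical
(sequence, config, seed) triples reproduce the search trace exactly. The
trace's wall-clock column is the one quantity outside that guarantee.

## Evaluation machinery

* `drmsd()` - distance-matrix RMSD over all residue pairs,
  $\sqrt{\sum_{i<j}(d^p_{ij}-d^n_{ij})^2 / \binom{n}{2}}$; no
  superposition is needed, so no Kabsch alignment is involved.
* `lattice_distance_matrix()` - scales lattice distances so one bond is
  3.8 Å. A bond's Euclidean length is $\sqrt 2$ lattice units (the printed
  "2" in the source description is the squared distance), so the factor is
  $3.8/\sqrt 2$.
* `relative_improvement()` - $(E_t - E_r)/E_r \times 100$; RMSD
  comparisons use the absolute value to match the published sign
  convention.
* `mann_whitney_u()` - rank-sum U with normal approximation and tie
  correction (delegated to `stats::wilcox.test`).
* `progress_summary()` - mean best-so-far energy per time interval across
  run traces.

## Fixtures and oracles

`load_benchmarks()` carries the 12 benchmark proteins verbatim with their
published reference energies, RMSDs and relative improvements;
`load_ablation()` and `load_contact_counts()` carry the four-variant
ablation tables. A checksum over the sequences is asserted at load. All 12
sequences count exactly to their printed lengths. The printed H-count
column disagrees with the hydrophobic classification for 9 of 12 proteins,
so the fixture exposes both the printed and the recomputed count and the
package treats the recomputed one as authoritative.

`enumerate_saws()` / `global_minimum()` enumerate every SAW of up to 10
residues with the first step frozen to $v_1$ - the FCC point group acts
transitively on the basis vectors, so this quotient cannot change counts of
distinct shapes per symmetry class or the optimum energy; no further
symmetry reduction is applied, keeping the oracle simple enough to be
obviously correct. The oracle prunes nothing, so its minimum is the true
global optimum and lower-bounds anything the GA returns.

## What the tests do and do not show

The test suite validates the machinery at desk scale, deliberately far from
the published 50-run x 60-minute cluster protocol:

* contact enumeration, both energies and class counts agree exactly with
  quadratic brute force on 100 fuzzed walks of up to 60 residues;
* every operator preserves the SAW invariant across more than 10 000
  fuzzed applications;
* pull-move reversibility is verified exhaustively for every chain of 2-8
  residues (about 1.35 million walks and 105 million pulls at length 8);
* the HP-model GA recovers the enumerated global optimum of an 8-residue
  sequence in at least 19 of 20 seeded runs (population 10, 30
  generations);
* on the smallest benchmark protein (4RXN, 54 residues), short seeded runs
  (population 20, 150 generations, 2 seeds per variant) reproduce the
  published qualitative ablation signal. At this scale the robust,
  asserted component is the gap between core-directed (BH) and
  energy-greedy (BD) macro-mutation; the BH/BM gap is small relative to
  seed noise at desk scale and is reported rather than asserted. At still
  shorter budgets (tens of generations) the ordering can invert - BD's
  greedy energy descent pays off immediately while BH's core formation
  needs time - so short-budget results say nothing about full-scale
  rankings.

None of this certifies behaviour on real proteins at full scale: the
benchmark energies in the fixture are reference values for comparison
reporting, not quantities the desk-scale suite re-derives.

## Known limitations

* The random-walk acceptance returns the input whenever the starting
  energy is zero, so stagnation recovery is inert on conformations without
  contacts (relevant only for toy sequences).
* Tilt offsets are restricted to single orthogonal basis vectors; longer
  parallel displacements are not attempted.
* RMSD-versus-native requires user-supplied native C-alpha coordinates
  (`read_native_ca()`); no structures are downloaded or shipped.
* The BM-model landscape at small $n$ has many near-degenerate minima;
  exhaustive-optimality checks there need substantially larger GA budgets
  than the HP model and are not part of the routine suite.
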