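# fccfold

Ab initio, coarse-grained protein structure prediction on the 3D
face-centred-cubic (FCC) lattice, for researchers studying simplified
protein folding models and lattice search heuristics.

A structure is a self-avoiding walk: each residue occupies one FCC lattice
point (12 neighbours per point, basis vectors `v1 = (1,1,0)` ...
`v12 = (-1,0,-1)`) and consecutive residues are lattice neighbours. A
conformation is scored by summing pairwise contact energies over all
non-consecutive residue pairs one lattice bond apart:

    E = sum_{i<j-1} c_ij * e_ij

with `e_ij` from either the binary hydrophobic-polar (HP) model (-1 per
hydrophobic-hydrophobic contact) or the empirical Berrera et al. 20x20
residue contact-potential matrix ("BM", shipped verbatim as `bm_matrix()`).

The search engine is a genetic algorithm that mixes the two resolutions:
the BM matrix scores and steers the search, while the HP classification
directs a *macro-mutation* operator that squeezes hydrophobic residues
towards the hydrophobic core centre (the centroid of the hydrophobic
residues). The GA applies operators exhaustively (a child replaces its
parent only when strictly better), keeps populations duplicate-free by
relative encoding, and recovers from stagnation with a pull-move random
walk constrained to stay close in energy (5-10%) but far in structure
(10-75% changed encoding positions). Four variants (`BH`, `BD`, `BM`,
`HP`) isolate the contribution of the hydrophobicity knowledge.

Also included: the five primitive operators (single-point crossover,
rotation, diagonal, pull and tilt moves), distance-matrix RMSD and
relative-improvement metrics, Mann-Whitney U comparison, progress-trace
summaries, the 12 benchmark proteins with literature reference values, and
exhaustive small-chain enumeration oracles.

## Worked example

```r
library(fccfold)

## a four-residue chain bent so the two phenylalanines touch
conf <- conformation("FSSF",
  coords = rbind(c(0,0,0), c(1,1,0), c(2,0,0), c(1,-1,0)))
conf
#> FCC lattice conformation: 4 residues
#>   sequence: FSSF
#>   encoding: 1,4,2
#>   E_BM = -2.47, E_HP = -1, contacts HH/HP/PP = 1/0/0
```

The single Phe-Phe contact contributes exactly the Phe-Phe entry of the
contact matrix (-2.467); under the HP model the same contact counts -1.

```r
## fold the smallest benchmark protein with the mixed-resolution variant
b   <- load_benchmarks()
cfg <- ga_config(variant = "BH", pop_size = 20, max_generations = 150,
                 seed = 201)
res <- ga_run(b$sequence[b$id == "4RXN"], cfg)
res
#> GA result (variant BH, 150 generations)
#>   best search energy: -149.230
#>   E_BM = -149.23, E_HP = -53
#>   contacts HH/HP/PP/total = 53/67/24/144
```

`res$trace` records one row per generation (operator, best and mean energy,
stagnation counter, random-walk events, elapsed seconds); the best-so-far
column is non-increasing by construction. Energies are comparable with the
published reference values in `load_benchmarks()` via
`relative_improvement()`; full-scale runs use much larger budgets
(population 100, hour-long wall clocks), so short runs land well above the
reference averages.

```r
relative_improvement(-162.72, -156.32)   # 4.09 (% energy improvement)
global_minimum(hp_sequence("HPHH"), "hp")$min_energy  # exhaustive optimum
```

A command-line front end is installed at
`system.file("scripts", "fold.R", package = "fccfold")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","fold.R",package="fccfold"))')" \
  --seq MKKYTCTVCGYIYNPEDGDPDNGVNPGTDFKDIPDDWVCPLCGVGKDQFEEVEE \
  --variant BH --pop 20 --generations 100 --seed 1 --out run1
```

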