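# ruggedpaths

Roughness and evolutionary path predictability of fitness landscapes.

## What this is for

A fitness landscape maps genotype sequences to fitness, with adjacency
given by single-site (Hamming-1) mutations.  Experimental combinatorial
mutant libraries, and model landscapes built from protein-folding physics,
both raise the same question: of the many mutational trajectories
connecting two genotypes, how many are accessible to evolution, and how
similar are the accessible ones to each other?  `ruggedpaths` is for
researchers who want to quantify that, on their own genotype–fitness
tables or on synthetic landscapes.

The package implements six landscape characteristics:

* **Roughness** — deviation from additivity of a peak-anchored additive
  model (residual sum of squares of the least-squares fit
  `f̂(x) = f(peak) + Σ c(site, state)`, scaled by the mean squared
  fitness); local roughness (per-node RMS fitness difference to
  neighbours, averaged); peak fraction (genotypes with no strictly fitter
  neighbour, over the landscape size); and mean graph distance to the
  *tree component* (genotypes with at most one fitter neighbour, on which
  uphill walks never branch).
* **Path predictability** — the monotonic path fraction
  `(1/(L−1)) Σ_x S_x / d_x!`, where `S_x` counts the simple paths from
  `x` to the main peak along which fitness strictly increases and `d_x!`
  is the total number of simple paths; and the mean path divergence of
  trajectory bundles, `Σ_ij P_i P_j D(p_i, p_j)`, where `D` is the
  symmetrised mean nearest-Hamming-distance between two paths and `P_i`
  are occurrence probabilities.

Around these sit: adaptive-walk sampling under the diploid Kimura
fixation probability `u = (1 − e^(−2s))/(1 − e^(−4 N_e s))` from the
neutral to the strong-selection limit, with a selection-pressure sweep
driven by the misfolding-cost fitness `f = −A(1−P)/P`; scrambled-landscape
permutation nulls with Z-scores; a generator of additive landscapes
perturbed by exponential differentials and tunable multiplicative or
Gaussian noise; and a desk-scale off-lattice heteropolymer folding
simulator (four monomer types, Lennard-Jones + screened-Coulomb pair
potential, over-damped Brownian dynamics, RMSD-clustered native
ensembles) whose folding probability defines fitness for landscape
assembly by mutational expansion.

## A worked example

```r
library(ruggedpaths)

set.seed(1)
ls <- generate_noisy_additive(5, noise = noise_spec(nu = 0.5))
ls
#> Fitness landscape: 32 genotypes, 5 sites, |alphabet| = 2
#>   fitness range [0.0950039, 1], main peak 00000

roughness_report(ls)
#> Landscape characteristics:
#>   deviation_from_additivity    0.14295
#>   variability_explained        0.85705
#>   local_roughness              0.235987
#>   n_peaks                      5
#>   peak_fraction                0.15625
#>   mean_tree_distance           0.78125
#>   monotonic_path_fraction      0.383065
#>   mean_path_divergence         0.172963

set.seed(2)
zscore(ls, "deviation_from_additivity", n_perm = 100)
#> deviation_from_additivity: original 0.14295,
#>   permutations 0.227048 +/- 0.0457675 (n = 100), Z = -1.837
```

The landscape is a 5-site binary cube whose additive backbone (peak
fitness 1, exponential substitution costs) was perturbed by mild
multiplicative noise.  The additive model leaves 14% of the squared
fitness unexplained; 38% of the simple mutational paths to the main peak
are fitness-monotonic; and the negative Z-score says the landscape is
smoother (more additive) than uncorrelated landscapes with the same
fitness values — the hallmark of correlated, mutation-robust landscapes.

Sweeping selection pressure (the product `N_e · A`) shows path divergence
falling from the neutral random-walk regime to the strong-selection
plateau:

```r
set.seed(3)
sw <- selection_sweep(ls, pressures = c(0.01, 1, 100), walks_per_start = 100)
vapply(sw, `[[`, numeric(1), "overall")
#>   0.01      1    100
#> 0.4313 0.2172 0.0913
```

Experimental tables load through `load_landscape()` — either an explicit
genotype column or the binary-library convention (one 0/1 column per
named substitution), with an optional decimal-log proxy transform (for
concentration-like assays) and min–max normalisation onto [0, 1].

A command-line front end is installed at
`inst/scripts/ruggedpaths.R` with subcommands `generate`, `metrics`,
`paths`, `walk`, `divergence`, `zscore`, and `replicate-toy`.

## The acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end synthetic analysis from scratch: it
generates the 4-noise-level × 20-seed family of noisy-additive
landscapes, computes all six characteristics per landscape, contrasts
them with scrambled copies, reports the rank correlations between
roughness and path divergence, and runs a selection-pressure sweep —
writing the JSON report to `--out` (side outputs land next to it).  All
randomness derives from `--seed`.

## Scope

Fitness is treated at the level of the genotype alphabet: no
nucleotide/codon mutation model, no polymorphic population dynamics, no
clonal interference.  The folding simulator is desk-scale by design —
landscape assembly at the scale of thousands of sequences with real
physics costs CPU-months and is out of scope; the assembly and search
algorithms are instead exercised against pluggable deterministic folding
oracles.
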