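---
title: "Landscape roughness and the predictability of evolutionary paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape roughness and the predictability of evolutionary paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruggedpaths)
```

## The question

If evolution were replayed from the same starting genotype, how similar
would the mutational trajectory be?  On a fitness landscape — a map from
genotype sequences to fitness, with adjacency given by single-site
(Hamming-1) mutations — the answer depends on the landscape's
*ruggedness*.  `ruggedpaths` quantifies both sides of this relationship:
four roughness statistics, and two path-predictability statistics defined
over mutational trajectories, together with the machinery to sample such
trajectories under population-genetic dynamics, to compare every statistic
against permutation null models, and to build landscapes either from a
tunable noisy-additive generator or from a coarse-grained protein-folding
simulator in which fitness is robustness to misfolding.

## The six landscape characteristics

Let the landscape hold $L$ genotypes with fitness $f(x)$, and let the
*main peak* be the genotype of maximal fitness (ties broken
lexicographically for reproducibility).

**Deviation from additivity.**  A peak-anchored additive model predicts
$\hat f(x) = f(\text{peak}) + \sum_i c_{i,x_i}$, one free coefficient per
(site, non-peak state) carried by the substitutions separating $x$ from
the peak.  Coefficients minimise the residual sum of squares; on
rank-deficient designs (sparse landscapes) the minimum-norm solution is
taken via the singular value decomposition, and coefficients are not
sign-constrained even though on a declining landscape they are typically
negative.  Deviation from additivity is the residual sum of squares scaled
by the sum of squared fitness values (no mean-centring), so that it is 0
for a perfectly additive landscape; its complement is the fraction of
fitness variability explained.

**Local roughness.**  For each genotype, the root-mean-square fitness
difference to its present neighbours, averaged arithmetically over
genotypes (per-node first, not per-edge — the two weightings differ on
landscapes of variable degree).

**Peak fraction.**  The number of genotypes with no *strictly* fitter
neighbour, divided by $L$.  Equal-fitness neighbours do not disqualify a
peak, so plateau members count as peaks.

**Mean distance to the tree component.**  The tree component is the set of
genotypes with at most one strictly fitter neighbour; uphill walks on it
never branch.  The statistic is the graph-shortest-path distance (within
the present genotype set — absent genotypes are inviable) from each
genotype to the nearest tree node, averaged over the landscape.  On a
complete additive landscape the tree component is exactly the peak and its
immediate neighbours.  Every connected component contains its own fitness
maximum, hence a tree node, so distances are always finite in practice;
the documented diameter + 1 fallback is defensive only.

**Monotonic path fraction.**  A *simple* path between genotypes differing
at $d$ sites changes each differing site exactly once, directly to its
target state — there are $d!$ of them for any alphabet size.  A
*monotonic* path is a simple path along which fitness strictly increases
(strict, because under strong selection neutral steps almost never fix;
plateau steps are therefore non-monotonic).  The statistic averages, over
all non-peak genotypes $x$, the fraction $S_x/d_x!$ of simple paths to the
main peak that are monotonic.  Counting uses dynamic programming over
subsets of the differing sites, which the tests hold equal to brute-force
enumeration of orderings.

**Mean path divergence.**  The divergence of two paths is the mean, over
the genotypes of one path, of the shortest Hamming distance to the other
path, symmetrised by averaging the two directions (the directed variant is
exposed as an option).  For a *bundle* of paths sharing start and end
points, with occurrence probabilities $P_i$, the bundle's mean divergence
is $\sum_{i,j} P_i P_j D(p_i, p_j)$ — the expected divergence of two
independent draws with replacement; the $i = j$ terms are included and
contribute zero.  Bundle divergences are averaged within groups of equal
start–end Hamming distance (a divergence profile), and the overall value
weights bundles by their observation counts.  Low divergence means the
accessible paths crowd together: evolution is predictable even when many
paths exist.

## Evolutionary dynamics

Trajectories are sampled in the low mutation-rate limit: each proposed
single-site mutation is fixed or lost before the next arises.  Fixation
follows the diploid Kimura formula
$u(s) = (1 - e^{-2s})/(1 - e^{-4 N_e s})$, with the exact limit
$1/(2N_e)$ at $s = 0$ and log-space branches for extreme arguments;
inviable mutants ($s = -\infty$) have $u = 0$.  Walks start at a non-peak
genotype and stop on reaching a genotype with no strictly fitter
neighbour, or at a step cap (such walks are flagged, excluded from
bundles, and counted).

Rather than literally proposing and rejecting, the sampler draws from the
embedded jump chain: the next fixed state is a present neighbour chosen
with probability proportional to its fixation probability.  This is
identical in path law to propose/reject (rejections only repeat the
current state) and does not stall at weak selection.  Two parameter-free
limits are provided: `strong_limit` (uniform choice among strictly fitter
neighbours — the limit in which all uphill steps are equally likely) and
`neutral_limit` (uniform choice among all present neighbours: a random
walk probing only the landscape's topology).

For landscapes whose fitness column is a folding probability $P$, the
misfolding-cost model assigns $f = -A(1 - P)/P$: the negative of the
expected number of misfolded copies produced before an abundance $A$ of
correctly folded copies is reached.  Selection coefficients are then
proportional to $A$, so the product $N_e A$ is the single selection-
pressure knob: `selection_sweep()` holds $N_e$ fixed (default 1000; the
published value of the source model is not available in the text we build
from) and sweeps $A$.  As pressure goes to zero every neighbour's $u \to
1/(2N_e)$ and the neutral random walk is recovered exactly; at high
pressure deleterious fixation probabilities underflow and the strong-
selection plateau emerges.  On landscapes with ordinary (already
normalised) fitness, selection coefficients are plain fitness differences
and $N_e$ alone sets the pressure; both conventions are available.

## Null models and the synthetic-landscape generator

**Scrambling.**  A scrambled landscape keeps the genotype set (hence the
topology) and permutes the fitness values uniformly at random — an
uncorrelated null with the same fitness distribution.  `zscore()` reports
how many permutation standard deviations the original landscape's
statistic lies from the mean of (by default) 100 scrambles; a zero
permutation SD yields an `NA` sentinel with a warning.

**Noisy-additive generator.**  The generator states a definite world:

* a designated peak with fitness exactly 1;
* one negative fitness differential per (site, non-peak state), drawn
  from an exponential distribution with rate `lambda_rate`;
* additive fitness = 1 + sum of the differentials of the substitutions
  separating a genotype from the peak;
* one noise perturbation per genotype (not per substitution): either
  multiplicative — multiply by $U^\nu$, $U \sim \mathrm{Uniform}(0,1)$ —
  or additive Gaussian of SD $\sigma$; the peak itself is not perturbed;
* genotypes with perturbed fitness $> 0$ are retained, and the landscape
  is restricted to the peak's connected component so that path statistics
  stay well defined.

The default `lambda_rate` equals the number of sites, so the mean
single-substitution fitness drop is $1/\mathrm{length}$ and the additive
fitness declines from 1 at the peak to about 0 at the antipode — on a
five-site landscape the fitness scale of a typical point is then a few
tenths, with the far half of the cube hovering near the positivity
cutoff.  This is a package choice where no published value exists; it is
made once and not tuned.  Multiplicative noise with
$\nu \in \{0.5, 1, 2, 4\}$ (20 seeds each) is the headline family:
$\nu = 0$ reproduces the exactly additive landscape and increasing $\nu$
increases the median deviation from additivity monotonically.  Additive
Gaussian noise is retained as an option.

One caveat the tests deliberately do not assert: the sign of the
correlation between *local roughness* and path divergence.  On large
landscapes whose fitness mass sits mostly below the characteristic value
where noise flattens rather than roughens the surface, local roughness
*falls* with noise and correlates positively with divergence; on the
desk-scale five-site family here, about half of the fitness mass sits
above that regime and the sign flips.  The three robust correlations —
divergence against deviation from additivity (negative), against peak
fraction (negative), and against mean tree distance (positive) — are the
ones asserted.

## The folding simulator

The folding module supplies fitness landscapes whose structure is
inherited from polymer physics rather than postulated.  A model protein is
a chain of point monomers of four types — hydrophobic (H), hydrophilic
(P), and charged (+/−) — with stiff harmonic springs (rest length $a$,
energy $\tfrac12 k T (r - a)^2$) between chain neighbours, and, between
all other pairs, a Lennard-Jones 12-6 term plus a Debye–Hückel screened
Coulomb term $A_{ij}/r^{12} - B_{ij}/r^6 + q_i q_j e^{-r/\lambda_D}/r$.
Every numeric coefficient is a `physics_config()` field.  The published
source of this model family does not print usable values in the text we
build from, so the defaults are chosen to satisfy the qualitative
orderings the model requires — the H–H attraction is the strongest
like-pair attraction (the solvent-mimicking hydrophobic effect), H–P is
repulsive and H–charged more so — and the constructor enforces those
orderings.  No quantitative claim in the package depends on the default
numbers.

Kinetics are over-damped Brownian dynamics: each coordinate moves by
$-\partial E/\partial x\,\Delta t$ plus Gaussian noise of variance
$2 T \Delta t$ (the standard convention; the coefficient 2 is itself a
config field).  Two numerical safeguards: the deterministic per-monomer
displacement is capped (`max_move`) to keep the explicit Euler scheme
stable near the Lennard-Jones core, and a *quench* ends with an L-BFGS
minimisation of the energy using the analytic gradient, because plain
zero-temperature Euler descent creeps along soft collective modes for
thousands of steps without meeting any sensible stationarity tolerance.
The minimisation makes quenched conformations well-defined local minima,
which is what the RMSD clustering that follows needs.

A sequence's *native structure ensemble* is the largest single-linkage
cluster, at RMSD radius $\delta$, of the conformations from repeated
quenches (single linkage, rather than requiring all pairwise distances
within $\delta$, because the mutual-clique reading is computationally
intractable and nothing in the construction requires it).  RMSD is
computed after optimal superposition (Kabsch, proper rotations only).
The ensemble's membership threshold is the median plus `mad_multiplier`
(default 3) times the raw median absolute deviation of nearest-neighbour
distances within the cluster; an all-identical ensemble degenerates to
threshold = median, and membership is non-strict so exact copies still
belong.  The folding probability of a sequence against a reference
ensemble is the fraction of fresh quenches landing within the threshold —
resolution $1/n_{\text{samples}}$.

Landscape assembly expands breadth-first from a robustly folding seed:
every single-substitution mutant (chain endpoints immutable, mimicking
the fixed charged termini) is scored against the *fixed* reference
ensemble of the seed's structure, included if $P \ge p_{\min}$, and
expanded in turn.  The examined/included bookkeeping is reported as
provenance.  A pluggable folding oracle lets the assembly and the
simulated-annealing search for compact robust folders (objective
$P/R_g^3$) run against deterministic mocks in tests, so the algorithms
are exercised without the physics.  Production-scale landscapes
(thousands of sequences with real physics) are out of scope by design:
each included sequence costs hundreds of quenches.

## What the synthetic world does and does not establish

The generator and the desk-scale folding simulator emulate the structure
of combinatorial fitness data: complete or filtered neighbourhoods of a
peak, exponentially distributed substitution costs, noise of tunable
character, positivity filtering.  They do not emulate measurement error
models of real assays, codon-level mutation bias (mutations act directly
on the monomer alphabet), linkage or polymorphism (the low mutation-rate
limit is assumed throughout), or landscapes large enough for the
asymptotic regime of some statistics.  A green test therefore establishes
internal correctness and the direction of the headline contrasts on the
stated synthetic world — not quantitative agreement with any particular
experimental system.

## Numerical choices collected

* Lexicographic (C-locale) tie-breaks for the main peak and all orderings.
* Fitness serialised with 17 significant digits; TSV round-trips are
  bit-exact.
* Experimental loader: decimal log as the proxy transform for
  concentration-like measurements; min–max normalisation onto [0, 1]
  applied after the transform by default (the reverse order is exposed);
  a single-valued landscape normalises to 0.
* Kimura formula via `expm1`/log-space branches; the neutral branch
  activates below $|4 N_e s| = 10^{-9}$.
* Additive fits via SVD pseudoinverse with relative tolerance $10^{-10}$.
* Walk sampling via the embedded jump chain (path-law equivalent to
  propose/reject).
* Bundle divergence via a vectorised unique-genotype distance table —
  algebraically identical to the pairwise definition, which the tests
  cross-check against scalar pair sums.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
ls <- generate_noisy_additive(5, noise = noise_spec(nu = 1))
roughness_report(ls)
zscore(ls, "peak_fraction", n_perm = 100)
sweep <- selection_sweep(ls, pressures = c(0.01, 1, 100),
                         walks_per_start = 100)
vapply(sweep, `[[`, numeric(1), "overall")
```

The `replicate_toy()` pipeline (also reachable as
`Rscript inst/scripts/ruggedpaths.R replicate-toy`) chains all of the
above — family generation, characteristics, scrambled contrasts,
correlations, and the pressure sweep — writing JSON reports from a single
root seed.
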