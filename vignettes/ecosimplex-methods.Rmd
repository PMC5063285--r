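---
title: "Methods: eco-evolutionary dynamics on the trade-off simplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eco-evolutionary dynamics on the trade-off simplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecosimplex)
```

## The model

`ecosimplex` simulates a community of `S` sexually reproducing species on a
saturated `L x L` square lattice. Every site always holds exactly one
individual (semelparity: a whole generation dies at once and is replaced),
and every individual carries two things: an immutable species label and a
phenotype `T = (T^1, ..., T^n)` on the trade-off simplex — `n` allocation
fractions in `[0, 1]` summing to 1, e.g. the shares of a plant's biomass
budget invested in roots, stems/leaves and flowers. Generalists sit near the
simplex centre; specialists near a vertex.

Competition is phenotype-mediated and local. The *complementarity* of two
individuals is their normalised L1 distance in trait space,

    c_ij = sum_k |T^k(i) - T^k(j)| / n,

so similar phenotypes (which exploit the same resources) have low
complementarity and compete strongly. An individual's (local)
complementarity is the average over its `K` spatial neighbours,
`C_i = sum_{j in nn(i)} c_ij / K`, where the neighbourhood is the two
Chebyshev shells around the site (`K = 24`; one shell, `K = 8`, is a
configuration choice). Reproductive *performance* is `exp(beta * C)`: the
parameter `beta >= 0` sets how strongly the environment punishes crowding in
niche space. At `beta = 0` performance is flat and the model reduces to
neutral drift.

One synchronous generation proceeds as follows. Every individual dies. For
each vacant site, a **mother** is drawn from the `K` neighbours of the site
with softmax probability `P(j) = exp(beta * C_j) / sum_j' exp(beta * C_j')`,
all complementarities being those of the pre-update grid. A **father** is
then drawn from all of the mother's conspecifics anywhere on the lattice,
with probability again proportional to `exp(beta * C_l)`. The offspring
inherits the mother's species label and the admixed phenotype

    T_new^k = eta * T_mother^k + (1 - eta) * T_father^k + xi^k,

with `eta ~ Uniform[0, 1]` drawn once per offspring and `xi` a sum-preserving
mutation (below) of scale `mu`. Species can go extinct; no new labels ever
arise (no speciation, no hybridisation).

### The mutation operator

To perturb a simplex point without leaving the unit-sum hyperplane, the
noise is built from cyclic differences of `n` i.i.d. Gaussians
`r^k ~ N(0, mu/2)`:

    xi^k = r^k - r^{k+1},   r^{n+1} = r^1.

The telescoping sum is zero *exactly*; each component has variance
`mu^2 / 2` and cyclically adjacent components covary at `-mu^2 / 4` (tested
against Monte-Carlo moments at 10^6 draws). If a perturbed component leaves
`[0, 1]` it is truncated to the bound and the truncated difference is added
to another component chosen uniformly at random, iterating until the vector
is valid; the repair preserves the sum and only moves the violating mass. A
cap of `100 * n` passes guards the loop, though violations are rare at the
default `mu = 0.025` and one pass almost always suffices.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `L` | lattice side | 64 | sites |
| `S` | initial species count | 16 | — |
| `n` | trait dimension | 3 | — |
| `beta` | competition strength | 10 | — |
| `mu` | trait variability per generation | 0.025 | trait fraction |
| `radius` | kernel shells (`K = (2r+1)^2 - 1`) | 2 (`K = 24`) | sites |
| `init_sigma` | initial per-component trait spread | 0.1 | trait fraction |

The `L = 64`, `K = 24`, `S = 16`, `beta = 10`, `mu = 0.025` set is the
headline configuration of the study this model implements; `beta` and `mu`
are the two free parameters that organise the phenomenology (fast
specialisation at large `beta`, small `mu`). `init_sigma` is not stated by
the source conditions; we fix 0.1 — wide enough that initial communities
overlap broadly around the simplex centre, narrow enough that no individual
starts specialised — and long-run outcomes are insensitive to it (the
per-species initialisation variant exists precisely to check that). Initial
trait scatter reuses the cyclic-difference generator (with generator scale
`sqrt(2) * init_sigma`, giving per-component sd `init_sigma`), so raw
vectors sum to 1 before repair.

## Design choices where the construction was open

* **Boundaries** are periodic by default: a torus keeps `K = 24` exact for
  every site. A bounded mode is provided for sensitivity checks; edge sites
  then normalise complementarity and softmax over their actual neighbours.
* **Update scheme**: synchronous (generational) by default, matching
  semelparity; a sequential mode (sites replaced one at a time in random
  order, complementarities recomputed against the current grid after every
  replacement) is available and kept for small lattices — it is O(N) more
  work per generation.
* **The admixture proportion `eta`** belongs to the offspring, not to each
  trait: one draw shared across components (a per-trait mode exists behind
  `eta_per_trait` for sensitivity analysis).
* **The father pool includes the mother.** A sole-surviving conspecific
  therefore selfs. Excluding her would sterilise single-survivor species and
  force their deterministic extinction, a behaviour the model is not meant
  to have.
* **Repair recipient**: the component receiving truncated mass is uniform
  among the other `n - 1`; repair iterates because redistribution can create
  a fresh violation.
* **Moran's index** (the supplementary definition is not printed): for each
  species with abundance >= 2 we compute the classical Moran statistic on
  its 0/1 occupancy indicator with binary kernel-adjacency weights, then
  average across species weighted by abundance. Random labels give the
  permutation null `-1/(N-1)`; conspecific clustering gives positive values.
* **Asymmetric reward** (functional form not printed): performance is
  multiplied by `w(T) = 1 + a * T^f`; `a = 0` recovers the symmetric model
  exactly.
* **Alternative competition kernels** (forms not printed): `exp(beta * C)`
  (default), `1 + beta * C`, and `exp(beta * (1 - (1 - C)^2))` — all
  strictly increasing in `C`, all flat at `beta = 0`.
* **Monoculture RC**: heterospecific pairs do not exist inside a
  monoculture, so `GC_inter(S = 1)` is measured across two *independent*
  realizations; `relative_complementarity()` demands the second grid
  explicitly rather than silently rerunning anything, and `run_ensemble()`
  pairs consecutive replicates.
* **Missing values** (Moran with < 2 species of abundance >= 2, GC_inter in
  a single monoculture, intraspecific distance with only singletons) are
  `NA` in memory and empty fields in files, never sentinel numbers.

## Numerical notes

* Softmax weights are computed as `exp(beta * (C - max C))`; the shift
  cancels in every normalisation and prevents overflow at large `beta`.
* All-pairs L1 sums (global complementarities, intraspecific distances,
  well-mixed complementarity) use the sorted-prefix-sum identity, O(N log N)
  per trait component instead of O(N^2); the test suite verifies equality
  with exhaustive double loops to 1e-12.
* Weighted sampling uses cumulative sums with `findInterval`; a pool whose
  weights underflow to zero (possible only at extreme `beta` under bounded
  boundaries) falls back to uniform sampling over the pool.
* All randomness flows through R's global RNG in a documented order
  (mothers site-by-site, fathers grouped by species label, admixture, then
  mutation), so a trajectory is bit-reproducible from `config$seed`, and
  ensemble replicate seeds are derived deterministically from a base seed.

## What the simulations emulate — and what they do not

The generator reproduces the *conditions of the computational study*:
saturated space, equal a-priori favourability of all trade-offs, purely
competitive interactions mediated by trait similarity, and heritable traits
with small mutational steps. It does not emulate real plant communities'
unsaturated landscapes, biomass/productivity accounting, positive
interactions, migration, environmental fluctuation, or phenotype-dependent
mating barriers. Passing tests therefore demonstrate the internal logic of
the eco-evolutionary mechanism — diversification driven by
competition-weighted parentage — not predictions for any particular field
system.

## Experiment scale and statistics

The packaged experiments run at a reduced "desk" scale chosen as this
package's default: `L = 32`, `R = 20` replicates, 200 generations (the
full-scale configuration `L = 64`, thousands of replicates remains a
configuration choice). At this scale the qualitative orderings the test
suite asserts — interspecies distance growth within 10 generations,
monoculture intraspecific variability exceeding mixtures', local
complementarity non-decreasing in `S`, relative complementarity larger for
mixtures, specialisation toward simplex corners between generations 10 and
100, and the asexual-vs-sexual intraspecific contrast — are detected by
one-sided tests at alpha = 0.01 with 20 replicates. "Non-decreasing in `S`"
is asserted as a significant S = 1 to S = 16 increase plus absence of any
significant decrease between consecutive community sizes, because local
complementarity saturates at large `S` and adjacent sizes need not differ
significantly.

## Known limitations

* With `n = 3` traits, long runs at strong competition collapse to about
  three specialist species; coexistence of phenotypically equivalent
  specialists at one corner occurs but is transient at desk scales.
* The spatial sign structure of conspecific avoidance is subtle. In our
  simulations at `beta = 10` the community Moran index is *suppressed by an
  order of magnitude* relative to `beta = 0` but settles at small positive
  values rather than crossing zero — local dispersal's clustering tendency
  is weakened, not inverted, by competition. This holds across lattice sizes
  16-64, horizons to 1000 generations, synchronous and sequential updating,
  per-shell decompositions, and a trait-valued variant of the index, so we
  report the suppression (and the clearly positive neutral baseline) as the
  robust signature; an index construction under which the sign itself flips
  may exist but is not determined by the printed definitions.
* Sequential updating recomputes complementarities after every single
  replacement; whether intermediate recomputation is the intended reading is
  unstated, and this choice makes sequential mode expensive on large
  lattices.
* The coexistence-time measurement groups species by single-linkage centroid
  distance with a user threshold `eps`; very diffuse species can chain into
  one group, so `eps` should stay well below typical interspecies distances
  (0.05 on the 2/n-scaled metric works well for `n = 3`).

## A worked run

```{r example, eval = FALSE}
cfg <- simulation_config(L = 16, S = 8, beta = 10, mu = 0.025,
                         generations = 50, seed = 42,
                         metric_generations = c(0L, 10L, 50L))
tr <- run_simulation(cfg)
tr$metrics
```

The trajectory records, per generation: surviving species, mean
inter/intraspecific centroid distances, local and global complementarities
(LC, GC, GC_intra, GC_inter), relative complementarity RC, Moran's index,
and the mean distance to the nearest simplex vertex (a specialisation
measure). Snapshots are plain CSV (`write_snapshot`), configurations plain
YAML (`write_config`), and `inst/cli/ecosimplex-cli.R` exposes `simulate`,
`ensemble`, `metrics` and `fixture` subcommands over the same functions.
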