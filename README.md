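# ecosimplex

Individual-based, spatially explicit simulation of **rapid phenotypic
diversification in communities of competing species**, with the full suite of
trait-based biodiversity indices needed to quantify it.

The package is for ecologists and theoreticians studying eco-evolutionary
feedbacks: how competition for resources, acting on heritable phenotypes over
a handful of generations, reorganises a community in both physical space and
niche space — producing species-level specialisation, local spatial
anti-structuring, and long-lived coexistence of phenotypically equivalent
species ("emergent neutrality").

## The model

A saturated `L × L` lattice holds one individual per site. Each individual
has a species label (one of `S`, fixed; species can go extinct but never
arise) and a phenotype **T** = (T¹, …, Tⁿ) on the trade-off simplex: Tᵏ ∈
[0, 1], Σₖ Tᵏ = 1 — e.g. the fractions of a plant's biomass budget allocated
to roots, stems/leaves and flowers. Competition between two individuals is
set by their trait **complementarity**

&nbsp;&nbsp;&nbsp;&nbsp;c\_ij = Σₖ |Tᵏ(i) − Tᵏ(j)| / n,

and an individual's local complementarity C\_i is the mean c\_ij over its
K = 24 lattice neighbours. Generations are non-overlapping: everyone dies,
and each vacant site is refilled by an offspring whose **mother** is drawn
from the site's K neighbours with probability

&nbsp;&nbsp;&nbsp;&nbsp;P(j) = e^{β C_j} / Σ_{j'} e^{β C_{j'}},

and whose **father** is drawn from the mother's conspecifics anywhere on the
lattice, again with weight e^{βC}. Offspring traits are an admixture
η·T_mother + (1−η)·T_father (η ~ U[0,1], one draw per offspring) plus
sum-preserving mutation noise ξᵏ = rᵏ − rᵏ⁺¹ (rᵏ i.i.d. Gaussian, sd μ/2,
cyclic), truncated-and-redistributed back onto the simplex when needed. Two
parameters organise everything: the competition strength **β** (β = 0 is
exactly neutral drift) and the trait variability **μ**.

Indices computed per generation: mean inter- and intraspecific trait
distances, local complementarity (LC), global complementarities (GC,
GC_intra, GC_inter), relative complementarity (RC = GC_inter − GC_intra), a
multi-species Moran's I of conspecific spatial structure, surviving-species
counts, and mean distance to the nearest simplex vertex (specialisation).
Model variants — asexual reproduction, well-mixed dispersal/competition,
biased trade-off rewards, alternative competition kernels, per-species
initial conditions — are pure configuration switches.

## A worked example

```r
library(ecosimplex)
cfg <- simulation_config(L = 16, S = 8, beta = 10, mu = 0.025,
                         generations = 50, seed = 42,
                         metric_generations = c(0L, 10L, 50L))
tr <- run_simulation(cfg)
tr$metrics
#>   generation S_surviving interspecies_distance intraspecific_distance     LC
#> 1          0           8               0.02074                0.10922 0.1106
#> 2         10           8               0.08752                0.04250 0.1160
#> 3         50           4               0.26695                0.03219 0.2173
#>       GC GC_intra GC_inter        RC    moran_I vertex_distance
#> 1 0.1106  0.11120   0.1105 -0.000738 -0.0004299          0.3743
#> 2 0.1177  0.04292   0.1466  0.103726  0.0089669          0.3728
#> 3 0.2155  0.03235   0.2809  0.248514 -0.0109708          0.3068
```

Reading the rows: at generation 0 the eight species are statistically
identical (interspecies centroid distance ≈ 0.02, within-species spread
0.11). By generation 10 the species have already pulled apart in trait space
(interspecies distance ×4, intraspecific spread halved, RC jumps from ≈ 0 to
0.10): rapid diversification. By generation 50 four species survive, far
apart in niche space (0.267), internally homogeneous (0.032), with local
complementarity nearly doubled — neighbours now exploit different resources
— and individuals measurably closer to the simplex corners
(`vertex_distance` 0.37 → 0.31): specialisation.

Ensembles and sweeps:

```r
ens <- run_ensemble(cfg, R = 20, base_seed = 1)     # mean ± sd of every index
exp <- diversification_experiment(S_values = c(1, 2, 4, 8, 16),
                                  beta_values = 10, mu_values = 0.025)
```

A thin command-line front end over the same functions lives at
`inst/cli/ecosimplex-cli.R` (`simulate`, `ensemble`, `metrics`, `fixture`
subcommands).

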