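---
title: "Scenario land-use change, ecosystem services and an SDG index: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scenario land-use change, ecosystem services and an SDG index: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esluc)
```

`esluc` chains seven stages into one reproducible analysis: synthetic
landscape generation, Markov + cellular-automata (CA) land-use simulation
under three development scenarios, four raster ecosystem-service (ES)
models, entropy-weight aggregation into a total-ES surface, global Moran's
I and Getis-Ord Gi* hot/cold-spot classification, and an ES-based
Sustainable Development Goal (SDG) index. This vignette documents the
models, their assumptions, the parameters that matter, and the design
choices made where the design was genuinely open.

## The synthetic landscape

Every stage is exercised on generated data, so the whole pipeline runs
without any download. The generator (`generator_config()`,
`generate_bundle()`) emulates a heterogeneous subtropical mountainous
landscape:

* **Random fields.** All continuous layers derive from white noise smoothed
  by circular FFT convolution with a Gaussian kernel
  (`gaussian_field()`). The kernel standard deviation
  (`correlation_length`, default 8 cells) is the single knob controlling
  spatial autocorrelation. Spectral synthesis would offer finer control of
  the covariance but adds nothing the downstream stages are sensitive to.
* **Terrain.** The DEM is one such field rescaled to 73–3056 m, a steep
  mountain span. At the default 128 × 128 × 30 m extent this produces
  steeper slopes than a real 3.8 km window would show; the RUSLE stage
  therefore sees aggressive topography, which is deliberate — it stresses
  the LS factor rather than flattering it.
* **Land use.** Six classes (farmland, forest, grassland, water, built-up,
  unused; codes 1–6). The first map fills class quotas greedily from
  elevation-preference scores perturbed by per-class noise fields, so class
  shares hit the configured proportions to within rounding while water and
  farmland sit low and forest sits high. Default shares (0.195, 0.536,
  0.248, 0.007, 0.013, 0.001) reproduce the class composition of a
  forest-dominated karst region. Later maps apply a 6 × 6 per-step drift
  matrix: for each ordered class pair, `round(count_i × drift[i,j])` cells
  flip, grown as connected patches around random seeds rather than
  salt-and-pepper, so the CA stage later faces realistic patch structure.
  Because the flip counts are deterministic given the matrix, the empirical
  cross-tabulation of consecutive maps recovers the generating matrix to
  within rounding — the basis of the transition-recovery check.
* **Climate.** Baseline precipitation increases with elevation plus
  correlated noise, clipped to 811–2000 mm/yr; potential evapotranspiration
  decreases with elevation (600–1600 mm/yr). Scenario climates are
  multiplicative perturbations of the baseline: precipitation × 1.08 /
  1.05 / 1.03 and PET × 1.02 / 1.05 / 1.09 for SSP126 / SSP245 / SSP585.
  These deltas are declared generator conditions, not downscaled model
  output: the low-emission pathway is the relatively wettest (precipitation
  growth outpacing PET), the high-emission pathway the most
  evaporation-dominated. All orderings reported by the analysis scripts are
  emergent consequences of these conditions and should be read as such.
* **Drivers.** Roads and a railway are jittered random-walk polylines,
  water sources random points; each is reduced to an exact Euclidean
  distance transform in metres. Population and GDP are smooth fields
  concentrating on low ground.

What the generator does **not** emulate: real class-boundary geometry
(field/forest edges follow administrative and cadastral lines, not noise
contours), climate seasonality, soil-property correlation with lithology,
and any real study-area geometry. Passing tests therefore demonstrate
algorithmic correctness and internal consistency, not predictive skill on
real rasters.

## Land-use simulation

The simulator is a simplified member of the FLUS/PLUS family:

1. **Calibration** — `estimate_transition_matrix()` cross-tabulates the two
   most recent maps. Classes absent at the first date get identity rows (no
   evidence ⇒ persistence).
2. **Demand** — `project_demand()` powers the matrix: a 5-year calibration
   interval and a 15-year horizon give power 3.
3. **Scenario weights** — each scenario carries per-class competitiveness
   weights (e.g. built-up 0.10 / 0.15 / 0.40 under SSP126 / SSP245 /
   SSP585). The weights act twice. First, `weight_adjusted_matrix()` scales
   the off-diagonal transition probabilities *into* class j by the weight
   of j and renormalises rows, tilting demand itself: the projected area of
   a class is then monotone in its weight by construction, which is the
   property a "development-scenario weight" should have and what makes the
   urban-expansion scenario gain the most built-up land. Second, the same
   weight multiplies the allocation score (below). A score-only reading of
   the weights was considered and rejected: under strict demand
   satisfaction it leaves allocated areas weight-independent, so scenarios
   would differ only through their conversion constraints.
4. **Suitability** — `fit_suitability()` is a multinomial-logistic
   classifier on elevation, slope, the three distance layers, population
   and GDP, trained on a 4 000-cell sample and predicted everywhere.
   Classes with fewer than 10 training cells fall back to their map
   frequency. Any monotone probabilistic classifier could stand behind the
   same contract; multinomial logistic is reproducible and has no
   hyperparameters to tune.
5. **Allocation** — `allocate()` grows patches iteratively. Each round,
   classes below target claim the best cells of classes above target along
   allowed transitions, scored by
   `suitability × (neighbourhood share + 0.01) × weight` with a seeded
   10⁻⁹-scale jitter breaking ties reproducibly. The neighbourhood share
   (a box filter of radius 2 cells) makes growth cling to existing patches;
   the 0.01 epsilon lets isolated high-suitability cells found new ones.
   Convergence tolerance is 1% of each class demand; if the conversion
   constraints make demand infeasible (e.g. under SSP126 built-up may only
   take from farmland and unused land), allocation stops and reports the
   signed per-class residual rather than silently rebalancing.
6. **Constraints** — SSP126 forbids forest/grassland/water → built-up;
   SSP245 freezes conversions out of built-up and water; SSP585 allows
   everything into built-up. These encode the scenarios' development logic
   and are editable per run.

Validation is a hindcast: calibrate on the first two generated dates,
allocate the third date's demand, and score the result against the actually
generated third map with overall accuracy and Cohen's kappa
(`agreement_stats()`). On synthetic data with a generator this well-behaved
the agreement is high (κ ≈ 0.96); the statistic is reported to demonstrate
the protocol, not as a claim about real-world skill.

## Ecosystem-service models

All four are deterministic per-cell raster models driven by a per-class
biophysical table (`default_biophysical_table()`), whose shipped values are
plausible magnitudes for a subtropical mountainous landscape and are
configuration, never measured facts.

**Water yield** follows the Budyko-curve formulation: available water
`AWC = min(MSD, RD) × PAWC`; seasonality parameter `ω = Z·AWC/P`; dryness
index `R = k_c·PET/P`; evapotranspiration fraction
`AET/P = (1 + ωR)/(1 + ωR + 1/R)`; yield `Y = (1 − AET/P)·P`. The
seasonal coefficient Z (default 3, dimensionless) shifts the curve between
winter- and summer-dominant rainfall regimes; maximum soil depth defaults
to 2000 mm. Ratios are evaluated with precipitation floored at 10⁻⁹ only
inside denominators, and P = 0 cells short-circuit to Y = 0, so the bounds
0 ≤ Y ≤ P hold everywhere including degenerate cells. Two closed forms pin
the implementation: ω = 0 gives AET/P = R/(1+R), and ω = R = 1 gives
AET/P = 2/3.

**Carbon storage** sums four per-class pool densities (above-ground,
below-ground, soil, dead organic matter; Mg C/ha) times the cell area in
hectares. It is pure bookkeeping, and the tests treat it as such.

**Habitat quality** is `Q = H × (1 − D^z/(D^z + k²))` with suitability H
per class, scaling exponent z = 2.5, and half-saturation constant k. The
pressure D is built InVEST-style — for each threat (built-up: 1500 m
maximum distance, exponential decay reaching ~0.05 at that distance,
weight 1.0; farmland: 1000 m, linear decay, weight 0.6), the decayed
distance to the nearest source is multiplied by the threat weight and the
receiving class's sensitivity, and contributions are summed. The default k
is half the maximum observed D on the map (the common practice when no
calibration data exist) and should be fixed explicitly when comparing maps
across scenarios; distances use an exact Euclidean distance transform.

**Soil retention** is the RUSLE factor product `SC = R·K·LS·C·P`, exactly
as the model equation is stated here. That right-hand side is the erosion
form of RUSLE; the conventional vegetated-retention form
`R·K·LS·(1 − C·P)` is available behind `retention_form = TRUE`, and the
package deliberately implements the stated product as the primary output
rather than guessing intent. LS uses a slope-only approximation,
`(len/22.13)^0.4 × (sinθ/0.0896)^1.3` with the slope length fixed at one
cell size — a stated approximation; no flow accumulation is routed.
Erosivity is a single-parameter power law on annual precipitation,
`R = 0.03·P^1.6`, monotone and zero at zero rainfall, with magnitudes
typical of wet subtropical climates.

## Aggregation and weighting

ES layers are min–max normalised per map. A constant layer normalises to
0.5 everywhere by declared convention (with a warning): it carries no
ordering information but must not break the weighted sum. Entropy weights
are computed over valid cells: shares `p_ij = x_ij/Σx_ij`, entropy
`e_j = −(1/ln n)Σ p ln p` with `0·ln 0 := 0`, weight
`w_j ∝ 1 − e_j`. Dispersed indicators get more weight; weights are
recomputed per date/scenario rather than frozen, so the weighting tracks
each period's own information content. The total-ES surface is the
weighted sum of the normalised layers.

## Spatial statistics

Weights default to binary queen contiguity on the raster lattice, the
focal cell included for Gi* (its convention), edge cells keeping reduced
neighbour sets; a distance-band scheme is available. Global Moran's I uses
the analytical expectation −1/(n−1) and the normality-assumption variance.
Gi* is evaluated exactly in its standardised form and classified by
two-sided normal critical values 1.645/1.960/2.576 into codes −3…3
(sign × confidence level 90/95/99%). No multiple-testing correction is
applied — the plain confidence coding is what the hot/cold-spot maps
report; cells are the analysis unit throughout.

## The SDG index

Only the per-service marginals of the ES → SDG target mapping are
published: habitat quality supports 10 goals / 29 targets, carbon storage
7 / 19, water yield 10 / 25, soil retention 2 / 9, with 12 goals supported
in total. The shipped 4 × 17 matrix
(`inst/extdata/sdg_support_matrix_synthetic.csv`) is a synthetic
reconstruction distributing target counts across goals consistently with
*all* of those marginals simultaneously; it is editable data, and
`support_marginals()` validates any replacement. Per-goal scores are the
support-weighted means of the normalised ES layers,
`SDG_j = Σ_i(ES̃_i·G_ij)/Σ_i G_ij`; the composite is their unweighted mean
over the 12 supported goals (all ES and goal weights set to 1). Goals with
zero support are dropped from the mean, never divided by.

## Numerical choices and degenerate inputs

* Ties in allocation scores: seeded uniform jitter of magnitude 10⁻⁹,
  far below any meaningful score difference, so determinism never distorts
  ranking.
* Land-use classes absent from calibration data: identity transition rows.
* Constant indicator layers: 0.5 after normalisation, uniform entropy
  contribution, warning emitted.
* Constant grids in Gi*: all z = 0, class 0, warning (S = 0 would divide).
* Zero-variance grids in Moran's I: explicit error — the statistic is
  undefined and silently returning 0 would hide a degenerate input.
* Demand infeasible under constraints: partial allocation plus signed
  residual report, never silent rebalancing.

## Problem sizes

The default analysis grid is 128 × 128 cells at 30 m — large enough for
patch structure, neighbourhood effects and stable spatial statistics, small
enough that the full five-stage analysis completes in seconds. The
transition-recovery check runs at 512 × 512, where rounding error in the
flip counts is far below the 0.02 tolerance. Brute-force oracles
(Moran, Gi*, kappa, entropy, degradation, goal scoring) run on 8 × 8 to
16 × 16 inputs where exhaustive evaluation is trivially affordable.

## Known limitations

* The allocator is a simplified patch grower: it reproduces
  demand-satisfaction, neighbourhood clustering and constraint behaviour,
  not the published PLUS software's exact patch-generation internals or its
  random-forest driver-importance machinery.
* The suitability model is stationary: one fit per baseline map serves all
  scenarios.
* LS without flow accumulation understates convergent-flow erosion.
* Scenario climate deltas are stylised multipliers, not downscaled climate
  model output; every cross-scenario ordering in the outputs is conditional
  on them.
* The SDG support matrix is a marginal-consistent reconstruction; per-goal
  (as opposed to composite) scores depend on how targets are distributed
  within the published row totals.
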