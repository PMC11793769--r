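# esluc

Scenario land-use simulation, ecosystem services and an SDG index on raster
landscapes.

`esluc` is for landscape ecologists and land-system modellers who want a
fully reproducible, self-contained version of a now-standard regional
analysis chain: simulate land-use change (LUC) under development scenarios,
assess ecosystem services (ES) on the resulting maps, aggregate them into a
total-ES surface, locate hot and cold spots, and score progress towards the
UN Sustainable Development Goals (SDGs) from the ES surfaces. Every stage
runs on seeded synthetic landscapes, so the whole pipeline — and its test
suite — needs no external data.

## What it computes

**Land-use simulation** (Markov + patch-growing cellular automata): a
transition matrix `M` is estimated by cross-tabulating two calibration maps;
per-class area demand is `a·(M_w)^t`, where `M_w` tilts off-diagonal flows
into class *j* by scenario weight `w_j`; demand is allocated spatially by
iterative patch growing with score `suitability × (neighbourhood share + ε)
× w`, under per-scenario conversion constraints (the sustainable-development
scenario SSP126 forbids ecological land → built-up; the urban-expansion
scenario SSP585 allows everything into built-up). Validation uses overall
accuracy and Cohen's κ.

**Four ES models** on each map:

- water yield (Budyko curve): `Y = (1 − AET/P)·P` with
  `AET/P = (1+ωR)/(1+ωR+1/R)`, `ω = Z·AWC/P`, `R = k_c·PET/P`,
  `AWC = min(MSD, RD)·PAWC`;
- carbon storage: `C_tot = C_above + C_below + C_soil + C_dead` per class,
  times cell area;
- habitat quality: `Q = H·(1 − D^z/(D^z + k²))`, `z = 2.5`, with pressure
  `D` summed from distance-decayed threats (built-up, farmland) weighted by
  per-class sensitivities;
- soil retention (RUSLE factors): `SC = R·K·LS·C·P`, with the
  `R·K·LS·(1−C·P)` retention variant behind a flag.

**Aggregation**: min–max normalisation, entropy weights
(`w_j ∝ 1 − e_j`, `e_j = −(1/ln n)Σ p ln p`), weighted total-ES surface.

**Spatial statistics**: global Moran's I and Getis-Ord Gi\* on queen
contiguity weights, z-scores classified into confidence codes −3…3
(sign × 90/95/99% level).

**SDG index**: per-goal score `SDG_j = Σ_i(ES̃_i·G_ij)/Σ_i G_ij` from an
ES × SDG target-support matrix `G` (shipped as a reconstruction consistent
with the published marginals: habitat quality 10 goals/29 targets, carbon
7/19, water 10/25, soil 2/9, 12 goals in total), composite = unweighted
mean over the 12 supported goals.

## Worked example

The five numbered scripts under `analysis/` run the full chain on a
128 × 128 synthetic mountain landscape (seed 2026). `analysis/02` prints
the scenario change table:

```
Area change vs baseline (km2):
   land_use SSP126_change SSP245_change SSP585_change
1  farmland       -0.0927       -0.0612       -0.1872
2    forest        0.0990       -0.0036       -0.0945
3 grassland       -0.1017       -0.1233       -0.1620
4     water        0.0360        0.0360        0.0351
5   builtup        0.0657        0.1575        0.4149
6    unused       -0.0063       -0.0054       -0.0063
```

Built-up growth is monotone in the scenario's built-up weight
(0.066 < 0.157 < 0.415 km², weights 0.10 < 0.15 < 0.40), and under SSP126
the allocator reports a 44-cell residual: ecological land may not convert
to built-up there, and once farmland's surplus is exhausted the remaining
demand is left explicitly unmet rather than silently rebalanced.
`analysis/03` summarises the ES response:

```
  SSP126: water +89.0 mm | carbon +874 Mg | habitat -0.0012 | soil +56.3
  SSP245: water +43.2 mm | carbon -1850 Mg | habitat -0.0070 | soil +33.3
  SSP585: water +10.8 mm | carbon -5545 Mg | habitat -0.0168 | soil -6.8
```

Water yield and soil retention rise most, and carbon and habitat decline
least, under the sustainable-development scenario — an ordering that
emerges from the scenario weights, constraints and climate deltas rather
than being coded anywhere. `analysis/04` finds strongly positive spatial
autocorrelation of total ES (Moran's I ≈ 0.81–0.84 across periods) and
classifies hot/cold spots; `analysis/05` scores the SDG composite
(regional mean 0.480 at baseline; 0.481 / 0.474 / 0.466 under
SSP126 / SSP245 / SSP585).

Each script is a thin driver over exported functions; everything it does
can be reproduced interactively, e.g.

```r
library(esluc)
bundle <- generate_bundle(generator_config(seed = 2026))
sim    <- simulate_scenario(bundle, "SSP585", horizon_steps = 3, seed = 2026)
panel  <- normalize_panel(compute_es_panel(bundle, landuse = sim$map))
w      <- entropy_weights(panel)
hot    <- getis_ord_gi_star(total_es(panel, w))
sdg    <- sdg_composite(sdg_scores(panel))
```

## Layout

- `R/` — all computation (generator, simulator, ES models, aggregation,
  spatial stats, SDG index, pipeline driver `run_demo()`)
- `analysis/01…05_*.R` — the narrative analysis sequence, writing to
  `results/`
- `inst/extdata/` — editable parameter tables (biophysical table, SDG
  support matrix reconstruction, published area table)
- `vignettes/ecosystem-service-scenarios.Rmd` — model assumptions, design
  decisions and limitations
- `tests/testthat/` — unit, property and acceptance suites with
  brute-force oracles
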