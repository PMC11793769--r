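#!/usr/bin/env Rscript
# SDG scoring: load the ES x SDG support matrix, check its marginals, score
# each supported goal from the normalised ES surfaces and average into the
# composite SDG index per period.

library(esluc)

SEED <- 2026L
dir.create("results", showWarnings = FALSE)

G <- load_support_matrix()
marg <- support_marginals(G)
cat("Support-matrix marginals (goals / targets per ES):\n")
print(marg$per_es, row.names = FALSE)
cat("Goals supported by at least one ES:", marg$n_goals_union, "\n\n")
write.csv(marg$per_es, "results/05_support_marginals.csv", row.names = FALSE)

config <- generator_config(seed = SEED, nrow = 128L, ncol = 128L)
bundle <- generate_bundle(config, n_dates = 3L)
baseline <- bundle$landuse_series$t3
suit <- fit_suitability(bundle, baseline, seed = SEED)

landuse <- list(baseline = baseline)
for (sc in c("SSP126", "SSP245", "SSP585"))
  landuse[[sc]] <- simulate_scenario(bundle, sc, 3L, seed = SEED,
                                     suitability = suit)$map

rows <- list()
for (label in names(landuse)) {
  clim <- generate_climate(config, bundle$dem,
                           if (label == "baseline") "baseline" else label)
  panel <- normalize_panel(
    compute_es_panel(bundle, landuse = landuse[[label]],
                     precip = clim$precip, pet = clim$pet))
  goals <- sdg_scores(panel, G)
  comp <- sdg_composite(goals)
  write_ascii_grid(comp$grid, sprintf("results/05_sdg_index_%s.asc", label))
  per_goal <- vapply(goals, function(g) mean(g$values, na.rm = TRUE),
                     numeric(1))
  rows[[label]] <- c(period = label, m = comp$m,
                     composite = round(comp$regional_mean, 4),
                     round(per_goal, 4))
}
tab <- as.data.frame(do.call(rbind, rows))
write.csv(tab, "results/05_sdg_scores.csv", row.names = FALSE)

cat("Regional mean SDG index per period (", tab$m[1], "goals ):\n")
print(tab[, c("period", "composite")], row.names = FALSE)
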