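#' Published scenario land-use area table
#'
#' Loads the shipped per-class area table (km2) for a 25-county karst
#' region in southeastern Yunnan: observed 2020 areas and simulated 2035
#' areas under three development scenarios. Change columns are recomputed
#' from the areas with [change_table()], never stored.
#'
#' @param path CSV override; `NULL` loads the shipped table.
#' @return data.frame as produced by [change_table()].
#' @export
reference_change_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_luc_areas_2035.csv",
                        package = "esluc", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("land_use", "area_2020", "SSP126", "SSP245", "SSP585")
                %in% names(df)))
  df <- df[match(LU_NAMES, df$land_use), ]
  base <- stats::setNames(df$area_2020, df$land_use)
  scen <- lapply(df[c("SSP126", "SSP245", "SSP585")],
                 function(a) stats::setNames(a, df$land_use))
  change_table(base, scen)
}

#' Run the full demonstration pipeline on a synthetic landscape
#'
#' Chains every stage: generate a seeded bundle; hindcast-validate the
#' allocator (calibrate on the first two land-use dates, allocate the last
#' date's demand, score agreement against the actually generated last map);
#' simulate each scenario to the horizon; compute the four
#' ecosystem-service surfaces per scenario under scenario climate; derive
#' entropy weights and the total-ES surface; run Moran's I and Gi*
#' hot/cold-spot classification; and score the SDG index. Writes a
#' machine-readable `summary.json`, CSV tables, and (optionally) every grid
#' as an ASCII raster. Fully reproducible: identical seeds give
#' byte-identical summaries.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param nrow,ncol synthetic grid size.
#' @param horizon_steps Markov steps from baseline to the scenario year.
#' @param scenarios character vector of scenario names.
#' @param write_grids write every raster as `.asc` (default TRUE).
#' @return invisibly, the summary list.
#' @export
run_demo <- function(out_dir, seed = 1L, nrow = 128L, ncol = 128L,
                     horizon_steps = 3L,
                     scenarios = c("SSP126", "SSP245", "SSP585"),
                     write_grids = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  config <- generator_config(seed = seed, nrow = nrow, ncol = ncol)
  bundle <- stage("generate", generate_bundle(config, n_dates = 3L))
  if (write_grids) write_bundle(bundle, file.path(out_dir, "bundle"))

  # hindcast validation: calibrate on t1->t2, allocate t3's demand, compare
  # against the generated t3
  valid <- stage("validate", {
    s <- bundle$landuse_series
    tm <- estimate_transition_matrix(s$t1, s$t2)
    suit <- fit_suitability(bundle, s$t2, seed = seed)
    demand <- project_demand(class_areas(s$t2), tm, 1L)
    model <- list(suitability = suit, weights = rep(1, 6),
                  constraints = matrix(TRUE, 6, 6),
                  neighbourhood_radius = 2L)
    hind <- allocate(s$t2, demand, model, seed = seed)
    agreement_stats(hind, s$t3)
  })

  baseline <- bundle$landuse_series[[length(bundle$landuse_series)]]
  suit <- stage("suitability", fit_suitability(bundle, baseline, seed = seed))

  sims <- list()
  for (sc in scenarios)
    sims[[sc]] <- stage(paste0("simulate:", sc),
                        simulate_scenario(bundle, sc, horizon_steps,
                                          seed = seed, suitability = suit))
  ct <- build_change_table(baseline, lapply(sims, `[[`, "map"))
  utils::write.csv(ct, file.path(out_dir, "change_table.csv"),
                   row.names = FALSE)

  analyse <- function(lu, precip, pet, label) {
    panel <- stage(paste0("es:", label),
                   compute_es_panel(bundle, landuse = lu,
                                    precip = precip, pet = pet))
    npanel <- normalize_panel(panel)
    w <- entropy_weights(npanel)
    tes <- total_es(npanel, w)
    mi <- stage(paste0("moran:", label), morans_i(tes))
    hs <- stage(paste0("gi_star:", label), getis_ord_gi_star(tes))
    goals <- sdg_scores(npanel)
    comp <- sdg_composite(goals)
    if (write_grids) {
      gdir <- file.path(out_dir, label)
      dir.create(gdir, showWarnings = FALSE)
      for (nm in names(panel))
        write_ascii_grid(panel[[nm]], file.path(gdir, paste0(nm, ".asc")))
      write_ascii_grid(tes, file.path(gdir, "total_es.asc"))
      write_ascii_grid(hs$classes, file.path(gdir, "hotspots.asc"))
      write_ascii_grid(comp$grid, file.path(gdir, "sdg_index.asc"))
    }
    cls <- hs$classes$values
    list(entropy_weights = as.list(round(w, 6)),
         morans_I = round(mi$I, 6), morans_z = round(mi$z, 4),
         hot_cells = sum(cls >= 1, na.rm = TRUE),
         cold_cells = sum(cls <= -1, na.rm = TRUE),
         sdg_regional_mean = round(comp$regional_mean, 6),
         sdg_goals = comp$m)
  }

  results <- list(baseline = analyse(baseline, bundle$precip_annual,
                                     bundle$pet_annual, "baseline"))
  for (sc in scenarios) {
    clim <- generate_climate(config, bundle$dem, sc)
    results[[sc]] <- analyse(sims[[sc]]$map, clim$precip, clim$pet, sc)
  }

  chg <- lapply(scenarios, function(sc) {
    stats::setNames(as.list(round(ct[[paste0(sc, "_change")]], 4)),
                    ct$land_use)
  })
  names(chg) <- scenarios

  summary <- list(
    seed = seed,
    grid = c(nrow, ncol),
    horizon_steps = horizon_steps,
    validation = list(kappa = round(valid$kappa, 4),
                      accuracy = round(valid$accuracy, 4)),
    change_km2 = chg,
    analysis = results)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
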