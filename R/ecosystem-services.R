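#' Default per-class biophysical parameter table
#'
#' One row per land-use class: vegetation evapotranspiration coefficient
#' `k_c`; the four carbon pool densities (Mg C/ha); habitat suitability
#' `habitat` (0-1) and per-threat sensitivities; RUSLE cover (`usle_c`) and
#' practice (`usle_p`) factors. The shipped values are plausible magnitudes
#' for a subtropical mountainous landscape and are configuration, not
#' measured facts; edit the CSV (`inst/extdata/biophysical_table.csv`) or
#' pass your own data.frame to override.
#'
#' @return data.frame with 6 rows keyed by `class` code 1-6.
#' @export
default_biophysical_table <- function() {
  data.frame(
    class = 1:6,
    name = LU_NAMES,
    k_c = c(0.65, 1.00, 0.85, 1.10, 0.30, 0.50),
    c_above = c(5, 120, 8, 0, 2, 1),
    c_below = c(8, 30, 20, 0, 1, 1),
    c_soil = c(90, 140, 100, 0, 30, 40),
    c_dead = c(1, 10, 2, 0, 0, 0),
    habitat = c(0.4, 1.0, 0.7, 0.9, 0.0, 0.3),
    sens_builtup = c(0.5, 0.9, 0.7, 0.6, 0.0, 0.4),
    sens_farmland = c(0.0, 0.6, 0.5, 0.4, 0.0, 0.2),
    usle_c = c(0.22, 0.003, 0.05, 0.0, 0.0, 0.35),
    usle_p = c(0.40, 1.00, 1.00, 0.0, 0.0, 1.00))
}

#' Read a biophysical table from CSV
#' @param path CSV with the columns of [default_biophysical_table()].
#' @return validated data.frame.
#' @export
read_biophysical_table <- function(path) {
  bt <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_biophysical_table(bt)
  bt
}

validate_biophysical_table <- function(bt) {
  need <- c("class", "k_c", "c_above", "c_below", "c_soil", "c_dead",
            "habitat", "usle_c", "usle_p")
  miss <- setdiff(need, names(bt))
  if (length(miss))
    stop("biophysical table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  frac <- c("habitat", "usle_c", "usle_p",
            grep("^sens_", names(bt), value = TRUE))
  for (cl in frac)
    if (any(bt[[cl]] < 0 | bt[[cl]] > 1, na.rm = TRUE))
      stop(sprintf("biophysical table: %s must lie in [0,1]", cl),
           call. = FALSE)
  if (any(bt[c("c_above", "c_below", "c_soil", "c_dead")] < 0))
    stop("biophysical table: carbon densities must be >= 0", call. = FALSE)
  invisible(TRUE)
}

# per-cell lookup of one biophysical column by land-use code
lu_lookup <- function(lu_values, biophys, column) {
  v <- rep(NA_real_, 7L)
  v[biophys$class] <- biophys[[column]]
  present <- sort(unique(lu_values[!is.na(lu_values)]))
  missing <- setdiff(present, biophys$class)
  if (length(missing))
    stop("biophysical table has no row for class(es) ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- matrix(NA_real_, nrow(lu_values), ncol(lu_values))
  ok <- !is.na(lu_values)
  out[ok] <- v[lu_values[ok]]
  out
}

#' Annual water yield from the Budyko-type curve
#'
#' Per cell: plant-available water `AWC = min(MSD, RD) x PAWC`; the
#' seasonality parameter `omega = Z x AWC / P`; the dryness index
#' `R = k_c x PET / P`; the evapotranspiration fraction
#' `AET/P = (1 + omega R) / (1 + omega R + 1/R)`; and yield
#' `Y = (1 - AET/P) x P`. Cells with zero precipitation yield 0 without any
#' division blow-up, and `0 <= Y <= P` everywhere.
#'
#' @param bundle a landscape_bundle (supplies precip, PET, root depth, PAWC
#'   unless overridden).
#' @param biophys biophysical table with `k_c`.
#' @param z seasonal coefficient Z (> 0, dimensionless; default 3).
#' @param msd maximum soil depth in mm (scalar or raster_grid; default
#'   2000).
#' @param landuse categorical raster_grid; default last map in the series.
#' @param precip,pet optional raster_grids overriding the bundle climate
#'   (e.g. scenario grids).
#' @return raster_grid of annual water yield in mm/yr.
#' @export
water_yield <- function(bundle, biophys = default_biophysical_table(),
                        z = 3, msd = 2000, landuse = NULL,
                        precip = NULL, pet = NULL) {
  if (z <= 0) stop("validation error: Z must be > 0", call. = FALSE)
  if (is.null(landuse))
    landuse <- bundle$landuse_series[[length(bundle$landuse_series)]]
  if (is.null(precip)) precip <- bundle$precip_annual
  if (is.null(pet)) pet <- bundle$pet_annual
  check_coregistered(list(landuse = landuse, precip = precip, pet = pet,
                          root_depth = bundle$root_depth,
                          pawc = bundle$pawc))
  P <- precip$values
  E0 <- pet$values
  if (any(P < 0, na.rm = TRUE) || any(E0 < 0, na.rm = TRUE))
    stop("validation error: negative precipitation or PET", call. = FALSE)
  kc <- lu_lookup(landuse$values, biophys, "k_c")
  msd_v <- if (is_raster_grid(msd)) msd$values else msd
  awc <- pmin(msd_v, bundle$root_depth$values) * bundle$pawc$values
  eps <- 1e-9
  Psafe <- pmax(P, eps)
  omega <- z * awc / Psafe
  R <- kc * E0 / Psafe
  aet_ratio <- ifelse(R > eps,
                      (1 + omega * R) / (1 + omega * R + 1 / R),
                      0)
  aet_ratio <- pmin(pmax(aet_ratio, 0), 1)
  Y <- ifelse(!is.na(P) & P <= 0, 0, (1 - aet_ratio) * P)
  grid_like(landuse, Y)
}

#' Carbon storage from per-class pool densities
#'
#' Per cell the four pools (above-ground, below-ground, soil, dead organic
#' matter) are summed and multiplied by the cell area in hectares.
#'
#' @param landuse categorical raster_grid.
#' @param biophys biophysical table with the four pool columns.
#' @return list with `grid` (Mg C per cell) and `total` (Mg C over valid
#'   cells).
#' @export
carbon_storage <- function(landuse, biophys = default_biophysical_table()) {
  dens <- lu_lookup(landuse$values, biophys, "c_above") +
    lu_lookup(landuse$values, biophys, "c_below") +
    lu_lookup(landuse$values, biophys, "c_soil") +
    lu_lookup(landuse$values, biophys, "c_dead")
  area_ha <- landuse$cell_size^2 / 1e4
  v <- dens * area_ha
  list(grid = grid_like(landuse, v), total = sum(v, na.rm = TRUE))
}

#' Threat specifications for the habitat model
#'
#' Each threat names a source land-use class, a maximum effective distance
#' in metres, a decay shape (`"exponential"` reaches ~0.05 at the maximum
#' distance; `"linear"` reaches 0), and a weight in [0,1]. Sensitivities of
#' receiving classes live in the biophysical table as `sens_<threat>`.
#'
#' @param name threat name matching a `sens_<name>` column.
#' @param source_class land-use code emitting the threat.
#' @param max_dist maximum effective distance (m, > 0).
#' @param decay `"exponential"` or `"linear"`.
#' @param weight threat weight in [0,1].
#' @return list of class `threat_spec`.
#' @export
threat_spec <- function(name, source_class, max_dist, decay = "exponential",
                        weight = 1) {
  if (max_dist <= 0)
    stop("validation error: max_dist must be > 0", call. = FALSE)
  if (!decay %in% c("exponential", "linear"))
    stop(sprintf("validation error: unknown decay shape '%s'", decay),
         call. = FALSE)
  if (weight < 0 || weight > 1)
    stop("validation error: threat weight must lie in [0,1]", call. = FALSE)
  structure(list(name = name, source_class = as.integer(source_class),
                 max_dist = max_dist, decay = decay, weight = weight),
            class = "threat_spec")
}

#' @rdname threat_spec
#' @export
default_threats <- function() {
  list(threat_spec("builtup", LU_CLASSES[["builtup"]], max_dist = 1500,
                   decay = "exponential", weight = 1.0),
       threat_spec("farmland", LU_CLASSES[["farmland"]], max_dist = 1000,
                   decay = "linear", weight = 0.6))
}

decay_fn <- function(d, max_dist, shape) {
  val <- switch(shape,
                linear = 1 - d / max_dist,
                exponential = exp(-2.99 * d / max_dist))
  ifelse(d > max_dist, 0, pmax(val, 0))
}

#' Habitat degradation from distance-decayed threats
#'
#' Cumulative land-use pressure: for each threat, the decayed distance to
#' the nearest source cell is multiplied by the threat weight and by the
#' receiving class's sensitivity, and the contributions are summed. A map
#' with no threat source cells degrades nowhere (D = 0).
#'
#' @param landuse categorical raster_grid.
#' @param threats list of [threat_spec()] objects.
#' @param biophys biophysical table carrying `sens_<threat>` columns.
#' @return raster_grid of dimensionless degradation D >= 0.
#' @export
habitat_degradation <- function(landuse, threats = default_threats(),
                                biophys = default_biophysical_table()) {
  lu <- landuse$values
  D <- matrix(0, nrow(lu), ncol(lu))
  for (th in threats) {
    col <- paste0("sens_", th$name)
    if (!col %in% names(biophys))
      stop(sprintf("biophysical table lacks sensitivity column '%s'", col),
           call. = FALSE)
    src <- !is.na(lu) & lu == th$source_class
    if (!any(src)) next
    d <- distance_to_cells(src, landuse$cell_size)
    sens <- lu_lookup(lu, biophys, col)
    D <- D + th$weight * decay_fn(d, th$max_dist, th$decay) * sens
  }
  D[is.na(lu)] <- NA
  grid_like(landuse, D)
}

#' Habitat quality
#'
#' `Q = H x (1 - D^z / (D^z + k^2))`: per-class habitat suitability H
#' degraded by a half-saturation response to the pressure D. With the
#' default z = 2.5, the penalty reaches one half where `D^z = k^2`.
#'
#' @param landuse categorical raster_grid.
#' @param D degradation raster_grid from [habitat_degradation()].
#' @param biophys biophysical table with `habitat`.
#' @param k half-saturation constant (> 0). Default: half the maximum
#'   observed D on the map (0.5 when D is identically 0).
#' @param z scaling exponent, default 2.5.
#' @return raster_grid of habitat quality in [0, 1].
#' @export
habitat_quality <- function(landuse, D, biophys = default_biophysical_table(),
                            k = NULL, z = 2.5) {
  if (is.null(k)) {
    dmax <- suppressWarnings(max(D$values, na.rm = TRUE))
    k <- if (is.finite(dmax) && dmax > 0) dmax / 2 else 0.5
  }
  if (k <= 0) stop("validation error: k must be > 0", call. = FALSE)
  H <- lu_lookup(landuse$values, biophys, "habitat")
  dz <- pmax(D$values, 0)^z
  grid_like(landuse, H * (1 - dz / (dz + k^2)))
}

#' Slope length-gradient (LS) factor
#'
#' Slope-only approximation with a fixed slope-length constant:
#' `LS = (len / 22.13)^0.4 x (sin(slope) / 0.0896)^1.3`. Flat terrain sits
#' at the factor's zero floor; LS is non-decreasing in slope.
#'
#' @param dem raster_grid of elevations.
#' @param slope_length effective slope length in metres (default the cell
#'   size).
#' @return raster_grid of dimensionless LS >= 0.
#' @export
ls_factor <- function(dem, slope_length = dem$cell_size) {
  sl <- slope_from_dem(dem)
  theta <- sl$values * pi / 180
  grid_like(dem, (slope_length / 22.13)^0.4 * (sin(theta) / 0.0896)^1.3)
}

#' Rainfall erosivity from annual precipitation
#'
#' Single-parameter power law `R = a x P^b`, monotone in precipitation and
#' zero where precipitation is zero. Defaults give magnitudes typical of wet
#' subtropical climates.
#'
#' @param precip raster_grid of annual precipitation (mm/yr, >= 0).
#' @param a,b coefficient and exponent of the power law.
#' @return raster_grid of erosivity (MJ mm / (ha h yr)).
#' @export
rainfall_erosivity <- function(precip, a = 0.03, b = 1.6) {
  P <- precip$values
  if (any(P < 0, na.rm = TRUE))
    stop("validation error: negative precipitation", call. = FALSE)
  grid_like(precip, a * P^b)
}

#' Soil retention (RUSLE factor product)
#'
#' Primary output is the factor product `SC = R x K x LS x C x P` exactly as
#' the model is stated; the conventional vegetated-retention form
#' `R x K x LS x (1 - C x P)` is available with `retention_form = TRUE`.
#'
#' @param bundle a landscape_bundle (supplies DEM and erodibility K).
#' @param biophys biophysical table with `usle_c`, `usle_p`.
#' @param erosivity raster_grid R; computed from the bundle's precipitation
#'   by default.
#' @param landuse categorical raster_grid; default last map in the series.
#' @param retention_form logical; use the `1 - C x P` variant.
#' @return raster_grid in t/(ha yr) units.
#' @export
soil_retention <- function(bundle, biophys = default_biophysical_table(),
                           erosivity = NULL, landuse = NULL,
                           retention_form = FALSE) {
  if (is.null(landuse))
    landuse <- bundle$landuse_series[[length(bundle$landuse_series)]]
  if (is.null(erosivity)) erosivity <- rainfall_erosivity(bundle$precip_annual)
  K <- bundle$erodibility_k$values
  R <- erosivity$values
  LS <- ls_factor(bundle$dem)$values
  if (any(K < 0, na.rm = TRUE) || any(R < 0, na.rm = TRUE))
    stop("validation error: negative RUSLE factor", call. = FALSE)
  C <- lu_lookup(landuse$values, biophys, "usle_c")
  P <- lu_lookup(landuse$values, biophys, "usle_p")
  v <- if (retention_form) R * K * LS * (1 - C * P) else R * K * LS * C * P
  grid_like(landuse, v)
}

#' Compute the four ecosystem-service surfaces for one land-use map
#'
#' Convenience wrapper chaining water yield, carbon storage, habitat quality
#' (with its degradation step) and soil retention on a shared bundle,
#' optionally under scenario climate grids.
#'
#' @param bundle a landscape_bundle.
#' @param landuse categorical raster_grid (default: last in the series).
#' @param biophys biophysical table.
#' @param threats threat list for the habitat model.
#' @param precip,pet optional scenario climate raster_grids.
#' @param z_coef seasonal coefficient for the water-yield model.
#' @return named list of raster_grids: `water_yield`, `carbon_storage`,
#'   `habitat_quality`, `soil_retention`.
#' @export
compute_es_panel <- function(bundle, landuse = NULL,
                             biophys = default_biophysical_table(),
                             threats = default_threats(),
                             precip = NULL, pet = NULL, z_coef = 3) {
  if (is.null(landuse))
    landuse <- bundle$landuse_series[[length(bundle$landuse_series)]]
  if (is.null(precip)) precip <- bundle$precip_annual
  wy <- water_yield(bundle, biophys, z = z_coef, landuse = landuse,
                    precip = precip, pet = pet)
  cs <- carbon_storage(landuse, biophys)
  D <- habitat_degradation(landuse, threats, biophys)
  hq <- habitat_quality(landuse, D, biophys)
  sr <- soil_retention(bundle, biophys,
                       erosivity = rainfall_erosivity(precip),
                       landuse = landuse)
  list(water_yield = wy, carbon_storage = cs$grid,
       habitat_quality = hq, soil_retention = sr)
}
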