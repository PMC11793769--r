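#' Land-use class codes
#'
#' The six land-use classes used throughout the pipeline, coded 1-6:
#' farmland, forest, grassland, water, built-up, unused.
#' @export
LU_CLASSES <- c(farmland = 1L, forest = 2L, grassland = 3L,
                water = 4L, builtup = 5L, unused = 6L)

#' @rdname LU_CLASSES
#' @export
LU_NAMES <- names(LU_CLASSES)

# Run code under a temporary RNG state so generators are pure functions of
# (config, seed) and never disturb the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic-landscape generator. The defaults are
#' the study conditions the rest of the pipeline is exercised under: a
#' mountainous landscape spanning 73-3056 m elevation, annual precipitation
#' confined to 811-2000 mm, six land-use classes with shares matching a
#' forest-dominated karst region, and a slow Markov drift from farmland /
#' grassland towards water and built-up land.
#'
#' @param seed integer master seed; every generated layer is a deterministic
#'   function of it.
#' @param nrow,ncol grid dimensions (cells).
#' @param cell_size metres per cell side.
#' @param correlation_length Gaussian smoothing length, in cells, of all
#'   random fields (>= 1).
#' @param class_proportions named length-6 vector of target class shares for
#'   the first land-use map; must sum to 1.
#' @param markov_drift 6x6 row-stochastic matrix of per-step (5-year)
#'   transition probabilities evolving the land-use series.
#' @param elevation_range,precip_range,pet_range numeric length-2 output
#'   spans (m, mm/yr, mm/yr).
#' @param climate_delta named list, one entry per scenario, each a list with
#'   `precip_add`, `precip_mult`, `pet_add`, `pet_mult` applied to the
#'   baseline climate.
#' @param patch_size mean size, in cells, of clustered change patches.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             nrow = 128L, ncol = 128L,
                             cell_size = 30,
                             correlation_length = 8,
                             class_proportions = c(
                               farmland = 0.195, forest = 0.536,
                               grassland = 0.248, water = 0.007,
                               builtup = 0.013, unused = 0.001),
                             markov_drift = default_markov_drift(),
                             elevation_range = c(73, 3056),
                             precip_range = c(811, 2000),
                             pet_range = c(600, 1600),
                             climate_delta = default_climate_delta(),
                             patch_size = 12) {
  if (nrow < 1L || ncol < 1L)
    stop("configuration error: grid dimensions must be positive",
         call. = FALSE)
  if (correlation_length < 1)
    stop("configuration error: correlation_length must be >= 1",
         call. = FALSE)
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("configuration error: class_proportions must sum to 1",
         call. = FALSE)
  validate_stochastic(markov_drift, what = "markov_drift")
  structure(list(
    seed = as.integer(seed), nrow = as.integer(nrow), ncol = as.integer(ncol),
    cell_size = cell_size, correlation_length = correlation_length,
    class_proportions = class_proportions, markov_drift = markov_drift,
    elevation_range = elevation_range, precip_range = precip_range,
    pet_range = pet_range, climate_delta = climate_delta,
    patch_size = patch_size), class = "generator_config")
}

validate_stochastic <- function(m, what = "matrix", tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != 6L || ncol(m) != 6L)
    stop(sprintf("configuration error: %s must be 6x6", what), call. = FALSE)
  if (any(m < 0))
    stop(sprintf("configuration error: %s has negative entries", what),
         call. = FALSE)
  rs <- rowSums(m)
  if (any(rs == 0))
    stop(sprintf("configuration error: %s has an all-zero row", what),
         call. = FALSE)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("configuration error: %s rows must sum to 1", what),
         call. = FALSE)
  invisible(TRUE)
}

#' @rdname generator_config
#' @export
default_markov_drift <- function() {
  m <- rbind(
    farmland  = c(0.975, 0.005, 0.005, 0.005, 0.009, 0.001),
    forest    = c(0.002, 0.990, 0.004, 0.002, 0.002, 0.000),
    grassland = c(0.005, 0.008, 0.978, 0.003, 0.005, 0.001),
    water     = c(0.002, 0.002, 0.002, 0.992, 0.002, 0.000),
    builtup   = c(0.001, 0.000, 0.000, 0.001, 0.998, 0.000),
    unused    = c(0.020, 0.030, 0.050, 0.010, 0.040, 0.850))
  colnames(m) <- LU_NAMES
  m
}

#' @rdname generator_config
#' @export
default_climate_delta <- function() {
  list(
    baseline = list(precip_add = 0, precip_mult = 1.00,
                    pet_add = 0, pet_mult = 1.00),
    SSP126   = list(precip_add = 0, precip_mult = 1.08,
                    pet_add = 0, pet_mult = 1.02),
    SSP245   = list(precip_add = 0, precip_mult = 1.05,
                    pet_add = 0, pet_mult = 1.05),
    SSP585   = list(precip_add = 0, precip_mult = 1.03,
                    pet_add = 0, pet_mult = 1.09))
}

#' Spatially autocorrelated Gaussian random field
#'
#' White noise smoothed by circular FFT convolution with a Gaussian kernel of
#' standard deviation `correlation_length` cells, then standardised to mean 0
#' and unit variance. The workhorse behind every synthetic layer.
#'
#' @param nrow,ncol grid dimensions.
#' @param correlation_length kernel standard deviation in cells.
#' @return numeric matrix, mean ~0, sd 1.
#' @export
gaussian_field <- function(nrow, ncol, correlation_length) {
  noise <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (correlation_length < 1e-9) return(noise)
  # wrap-around squared distances to cell (1,1)
  dr <- pmin(0:(nrow - 1), nrow - 0:(nrow - 1))
  dc <- pmin(0:(ncol - 1), ncol - 0:(ncol - 1))
  k <- exp(-outer(dr^2, dc^2, `+`) / (2 * correlation_length^2))
  k <- k / sum(k)
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(k), inverse = TRUE)) /
    (nrow * ncol)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic DEM
#'
#' A smooth spatially autocorrelated surface rescaled linearly to the
#' configured elevation span (default 73-3056 m, a steep mountainous
#' landscape). Deterministic under a fixed seed.
#'
#' @param config a [generator_config()].
#' @return raster_grid of elevations in metres.
#' @export
generate_dem <- function(config) {
  f <- with_seed(config$seed + 101L,
                 gaussian_field(config$nrow, config$ncol,
                                config$correlation_length))
  r <- config$elevation_range
  v <- (f - min(f)) / (max(f) - min(f)) * (r[2] - r[1]) + r[1]
  raster_grid(v, config$cell_size)
}

# elevation-preference scores per class: water/farmland/built-up favour low
# ground, forest and unused favour high ground, grassland mid-slopes
class_affinity <- function(e) {
  cbind(farmland  = -1.5 * e,
        forest    = 1.5 * e,
        grassland = -4 * (e - 0.6)^2,
        water     = -4.0 * e,
        builtup   = -2.5 * e,
        unused    = 2.0 * e)
}

#' Generate a Markov-consistent land-use time series
#'
#' The first map assigns classes by a greedy quota fill over
#' elevation-preference scores perturbed by per-class autocorrelated noise,
#' so class shares hit `class_proportions` to within rounding while water and
#' farmland sit low and forest sits high. Each subsequent map applies the
#' configured `markov_drift`: for every ordered class pair (i, j), i != j,
#' `round(count_i * drift[i, j])` cells change, flipped in spatially
#' clustered patches grown around random seeds rather than i.i.d., so the
#' cellular-automata stage later faces realistic patch structure.
#'
#' @param config a [generator_config()].
#' @param dem raster_grid from [generate_dem()].
#' @param n_dates number of maps in the series (>= 2 for a usable series).
#' @return named list of integer raster_grids ("t1", "t2", ...).
#' @export
generate_landuse_series <- function(config, dem, n_dates = 3L) {
  if (n_dates < 1L)
    stop("configuration error: n_dates must be >= 1", call. = FALSE)
  validate_stochastic(config$markov_drift, "markov_drift")
  with_seed(config$seed + 202L, {
    first <- initial_landuse(config, dem)
    out <- vector("list", n_dates)
    out[[1L]] <- first
    if (n_dates > 1L)
      for (t in 2L:n_dates)
        out[[t]] <- evolve_landuse(out[[t - 1L]], config$markov_drift,
                                   config$patch_size)
    names(out) <- paste0("t", seq_len(n_dates))
    lapply(out, function(m) raster_grid(m, config$cell_size))
  })
}

initial_landuse <- function(config, dem) {
  nr <- config$nrow; nc <- config$ncol; n <- nr * nc
  e <- dem$values
  e <- (e - min(e)) / (max(e) - min(e))
  sc <- class_affinity(as.vector(e))
  for (k in 1:6)
    sc[, k] <- sc[, k] + 0.8 * as.vector(
      gaussian_field(nr, nc, config$correlation_length / 2))
  quota <- round(config$class_proportions * n)
  quota[which.max(quota)] <- quota[which.max(quota)] + (n - sum(quota))
  # greedy fill: best (cell, class) pairs first, respecting class quotas
  ord <- order(as.vector(sc), decreasing = TRUE)
  cls_of <- (ord - 1L) %/% n + 1L
  cell_of <- (ord - 1L) %% n + 1L
  lu <- integer(n)
  left <- as.integer(quota)
  taken <- 0L
  for (p in seq_along(ord)) {
    i <- cell_of[p]; k <- cls_of[p]
    if (lu[i] == 0L && left[k] > 0L) {
      lu[i] <- k; left[k] <- left[k] - 1L; taken <- taken + 1L
      if (taken == n) break
    }
  }
  matrix(lu, nr, nc)
}

# one Markov step with clustered change patches
evolve_landuse <- function(lu, drift, patch_size) {
  nr <- nrow(lu); nc <- ncol(lu)
  out <- lu
  changed <- matrix(FALSE, nr, nc)
  counts <- tabulate(lu, 6L)
  for (i in 1:6) {
    if (counts[i] == 0L) next
    for (j in 1:6) {
      if (i == j) next
      need <- round(counts[i] * drift[i, j])
      while (need > 0L) {
        avail <- which(out == i & !changed)
        if (length(avail) == 0L) break
        seed_idx <- avail[sample.int(length(avail), 1L)]
        s <- max(1L, stats::rpois(1L, patch_size))
        s <- min(s, need, length(avail))
        sr <- (seed_idx - 1L) %% nr + 1L
        sc <- (seed_idx - 1L) %/% nr + 1L
        # grow within an expanding Chebyshev window around the seed
        w <- 1L
        repeat {
          rr <- max(1L, sr - w):min(nr, sr + w)
          cc <- max(1L, sc - w):min(nc, sc + w)
          sub <- out[rr, cc] == i & !changed[rr, cc]
          if (sum(sub) >= s || (length(rr) == nr && length(cc) == nc)) break
          w <- w * 2L
        }
        loc <- which(sub, arr.ind = TRUE)
        d <- pmax(abs(rr[loc[, 1L]] - sr), abs(cc[loc[, 2L]] - sc))
        take <- loc[order(d)[seq_len(min(s, nrow(loc)))], , drop = FALSE]
        ridx <- rr[take[, 1L]]; cidx <- cc[take[, 2L]]
        flat <- (cidx - 1L) * nr + ridx
        out[flat] <- j
        changed[flat] <- TRUE
        need <- need - length(flat)
      }
    }
  }
  out
}

#' Generate scenario climate grids
#'
#' Baseline precipitation increases with elevation plus correlated noise and
#' is clipped to the configured range; potential evapotranspiration decreases
#' with elevation. Scenario grids are the baseline transformed by the
#' configured per-scenario `climate_delta` (additive then multiplicative),
#' clipped back to the configured range.
#'
#' @param config a [generator_config()].
#' @param dem raster_grid from [generate_dem()].
#' @param scenario one of the names of `config$climate_delta`
#'   (baseline, SSP126, SSP245, SSP585 by default).
#' @param clip clamp outputs to the configured ranges (default TRUE); turn
#'   off to inspect the raw perturbed fields.
#' @return list with raster_grids `precip` and `pet` (mm/yr).
#' @export
generate_climate <- function(config, dem, scenario = "baseline",
                             clip = TRUE) {
  if (!scenario %in% names(config$climate_delta))
    stop(sprintf("validation error: unknown scenario '%s'", scenario),
         call. = FALSE)
  e <- dem$values
  e <- (e - min(e)) / (max(e) - min(e))
  f <- with_seed(config$seed + 303L,
                 gaussian_field(config$nrow, config$ncol,
                                config$correlation_length))
  pr <- config$precip_range
  base_p <- pr[1] + (0.15 + 0.65 * e + 0.20 * stats::pnorm(f)) *
    (pr[2] - pr[1])
  tr <- config$pet_range
  base_t <- tr[2] - 0.7 * e * (tr[2] - tr[1]) +
    0.1 * stats::pnorm(-f) * (tr[2] - tr[1])
  d <- config$climate_delta[[scenario]]
  p <- (base_p + d$precip_add) * d$precip_mult
  t <- (base_t + d$pet_add) * d$pet_mult
  if (clip) {
    p <- pmin(pmax(p, pr[1]), pr[2])
    t <- pmin(pmax(t, tr[1]), tr[2])
  }
  list(precip = raster_grid(p, config$cell_size),
       pet = raster_grid(t, config$cell_size))
}

# a jittered random walk from one grid edge to the opposite one
random_polyline <- function(nr, nc) {
  horizontal <- stats::runif(1) < 0.5
  len <- if (horizontal) nc else nr
  pos <- numeric(len)
  pos[1] <- stats::runif(1, 1, if (horizontal) nr else nc)
  for (k in 2:len)
    pos[k] <- min(max(pos[k - 1] + stats::rnorm(1, 0, 1.5), 1),
                  if (horizontal) nr else nc)
  if (horizontal) cbind(row = round(pos), col = seq_len(len))
  else cbind(row = seq_len(len), col = round(pos))
}

#' Generate driver layers
#'
#' Seeds random linear features (roads, railway) and point clusters (water
#' sources), returns their exact Euclidean distance transforms in metres,
#' plus smooth population and GDP density surfaces that concentrate on low
#' ground. Deterministic under the config seed.
#'
#' @param config a [generator_config()].
#' @param dem optional raster_grid; when supplied, population and GDP decay
#'   with elevation.
#' @return named list of raster_grids: `dist_road`, `dist_rail`,
#'   `dist_water`, `population`, `gdp`.
#' @export
generate_drivers <- function(config, dem = NULL) {
  nr <- config$nrow; nc <- config$ncol
  with_seed(config$seed + 404L, {
    mask_from <- function(pts) {
      m <- matrix(FALSE, nr, nc)
      m[cbind(pmin(pmax(pts[, 1], 1), nr), pmin(pmax(pts[, 2], 1), nc))] <- TRUE
      m
    }
    roads <- mask_from(do.call(rbind, replicate(3, random_polyline(nr, nc),
                                                simplify = FALSE)))
    rail <- mask_from(random_polyline(nr, nc))
    wpts <- cbind(sample.int(nr, 6, replace = TRUE),
                  sample.int(nc, 6, replace = TRUE))
    waterf <- mask_from(wpts)
    e <- if (is.null(dem)) matrix(0.5, nr, nc) else {
      z <- dem$values; (z - min(z)) / (max(z) - min(z))
    }
    popf <- gaussian_field(nr, nc, config$correlation_length)
    gdpf <- gaussian_field(nr, nc, config$correlation_length)
    pop <- exp(1.0 * popf - 2 * e); pop <- pop / mean(pop) * 100
    gdp <- exp(1.0 * gdpf - 2 * e); gdp <- gdp / mean(gdp) * 100
    cs <- config$cell_size
    list(
      dist_road = raster_grid(distance_to_cells(roads, cs), cs),
      dist_rail = raster_grid(distance_to_cells(rail, cs), cs),
      dist_water = raster_grid(distance_to_cells(waterf, cs), cs),
      population = raster_grid(pop, cs),
      gdp = raster_grid(gdp, cs))
  })
}

#' Assemble a complete synthetic landscape bundle
#'
#' Chains the individual generators into the co-registered stack every
#' downstream stage consumes: a land-use time series, terrain, baseline
#' climate, soil properties and driver layers.
#'
#' @param config a [generator_config()].
#' @param n_dates number of land-use maps in the series.
#' @return list of class `landscape_bundle` with elements `landuse_series`,
#'   `dem`, `slope`, `precip_annual`, `pet_annual`, `erodibility_k`,
#'   `root_depth`, `pawc`, `drivers`, `config`.
#' @export
generate_bundle <- function(config, n_dates = 3L) {
  dem <- generate_dem(config)
  lus <- generate_landuse_series(config, dem, n_dates)
  clim <- generate_climate(config, dem, "baseline")
  drv <- generate_drivers(config, dem)
  soils <- with_seed(config$seed + 505L, {
    kf <- stats::pnorm(gaussian_field(config$nrow, config$ncol,
                                      config$correlation_length))
    rf <- stats::pnorm(gaussian_field(config$nrow, config$ncol,
                                      config$correlation_length))
    pf <- stats::pnorm(gaussian_field(config$nrow, config$ncol,
                                      config$correlation_length))
    list(k = 0.10 + 0.40 * kf,        # RUSLE K, plausible span
         rd = 300 + 1700 * rf,        # root depth, mm
         pawc = 0.05 + 0.25 * pf)     # plant-available water, fraction
  })
  cs <- config$cell_size
  b <- structure(list(
    landuse_series = lus,
    dem = dem,
    slope = slope_from_dem(dem),
    precip_annual = clim$precip,
    pet_annual = clim$pet,
    erodibility_k = raster_grid(soils$k, cs),
    root_depth = raster_grid(soils$rd, cs),
    pawc = raster_grid(soils$pawc, cs),
    drivers = drv,
    config = config), class = "landscape_bundle")
  validate_bundle(b)
  b
}

#' Validate a landscape bundle
#'
#' Enforces the bundle invariants: co-registration of all layers, land-use
#' codes restricted to the six declared classes, non-negative slope, and
#' precipitation inside the configured generator range.
#'
#' @param bundle a landscape_bundle.
#' @return invisibly TRUE; errors otherwise.
#' @export
validate_bundle <- function(bundle) {
  layers <- c(bundle$landuse_series,
              bundle[c("dem", "slope", "precip_annual", "pet_annual",
                       "erodibility_k", "root_depth", "pawc")],
              bundle$drivers)
  check_coregistered(layers)
  for (lu in bundle$landuse_series) {
    v <- lu$values[!is.na(lu$values)]
    if (!all(v %in% 1:6))
      stop("bundle invariant violated: land-use codes outside 1..6",
           call. = FALSE)
  }
  if (any(bundle$slope$values < 0, na.rm = TRUE))
    stop("bundle invariant violated: negative slope", call. = FALSE)
  pr <- bundle$config$precip_range
  pv <- bundle$precip_annual$values
  if (any(pv < pr[1] - 1e-6 | pv > pr[2] + 1e-6, na.rm = TRUE))
    stop("bundle invariant violated: precipitation outside configured range",
         call. = FALSE)
  invisible(TRUE)
}

#' Write a bundle to a directory of ASCII grids plus a manifest
#'
#' One `.asc` file per layer (categorical layers as integers) and a
#' `manifest.json` recording layer names, class codes and generator settings.
#'
#' @param bundle a landscape_bundle.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(g, nm) write_ascii_grid(g, file.path(dir, paste0(nm, ".asc")))
  for (nm in names(bundle$landuse_series))
    wr(bundle$landuse_series[[nm]], paste0("landuse_", nm))
  for (nm in c("dem", "slope", "precip_annual", "pet_annual",
               "erodibility_k", "root_depth", "pawc"))
    wr(bundle[[nm]], nm)
  for (nm in names(bundle$drivers)) wr(bundle$drivers[[nm]], nm)
  manifest <- list(
    classes = as.list(LU_CLASSES),
    landuse_dates = names(bundle$landuse_series),
    cell_size = bundle$dem$cell_size,
    seed = bundle$config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
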