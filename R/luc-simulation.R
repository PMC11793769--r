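#' Estimate a Markov transition matrix from two land-use maps
#'
#' Cross-tabulates co-registered maps cell by cell and row-normalises:
#' entry (i, j) is the fraction of class-i cells at the first date that are
#' class j at the second. Classes absent at the first date get an identity
#' row (no evidence of change implies persistence).
#'
#' @param lu_t1,lu_t2 categorical raster_grids (codes 1-6).
#' @return 6x6 row-stochastic matrix with class-name dimnames.
#' @export
estimate_transition_matrix <- function(lu_t1, lu_t2) {
  if (!same_geometry(lu_t1, lu_t2))
    stop("estimation error: maps are not co-registered", call. = FALSE)
  a <- lu_t1$values; b <- lu_t2$values
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop("estimation error: no overlapping valid cells", call. = FALSE)
  m <- matrix(0, 6, 6, dimnames = list(LU_NAMES, LU_NAMES))
  tab <- table(factor(a[ok], levels = 1:6), factor(b[ok], levels = 1:6))
  m[] <- as.numeric(tab)
  rs <- rowSums(m)
  for (i in 1:6) {
    if (rs[i] > 0) m[i, ] <- m[i, ] / rs[i]
    else { m[i, ] <- 0; m[i, i] <- 1 }
  }
  m
}

#' Project per-class area demand with a Markov chain
#'
#' Row vector of current areas times the matrix power: the expected class
#' composition after `steps` transitions. Total area is conserved because
#' the matrix is row-stochastic.
#'
#' @param areas_now named numeric length-6, current class areas in km2.
#' @param matrix 6x6 row-stochastic transition matrix.
#' @param steps number of Markov steps (>= 0).
#' @return named numeric length-6 of projected areas (km2).
#' @export
project_demand <- function(areas_now, matrix, steps = 1L) {
  validate_stochastic(matrix, "transition matrix")
  if (steps < 0) stop("validation error: steps must be >= 0", call. = FALSE)
  v <- matrix(as.numeric(areas_now), nrow = 1)
  for (s in seq_len(steps)) v <- v %*% matrix
  stats::setNames(as.numeric(v), LU_NAMES)
}

#' Scenario definitions: weights and conversion constraints
#'
#' Three development scenarios with per-class competitiveness weights
#' (sustainable development SSP126, natural growth SSP245, urban expansion
#' SSP585) and per-scenario conversion-constraint matrices:
#' SSP126 forbids forest, grassland and water converting to built-up land;
#' SSP245 freezes conversions out of built-up land and water but allows all
#' others; SSP585 allows every conversion into built-up land.
#'
#' @return named list per scenario with elements `weights` (length 6) and
#'   `constraints` (6x6 logical, entry (i, j) = conversion i to j allowed).
#' @export
scenario_definitions <- function() {
  allow_all <- matrix(TRUE, 6, 6, dimnames = list(LU_NAMES, LU_NAMES))
  c126 <- allow_all
  c126[c("forest", "grassland", "water"), "builtup"] <- FALSE
  c245 <- allow_all
  c245["builtup", ] <- FALSE; c245["builtup", "builtup"] <- TRUE
  c245["water", ] <- FALSE; c245["water", "water"] <- TRUE
  list(
    SSP126 = list(
      weights = c(farmland = 0.20, forest = 0.40, grassland = 0.20,
                  water = 0.05, builtup = 0.10, unused = 0.05),
      constraints = c126),
    SSP245 = list(
      weights = c(farmland = 0.25, forest = 0.30, grassland = 0.20,
                  water = 0.05, builtup = 0.15, unused = 0.05),
      constraints = c245),
    SSP585 = list(
      weights = c(farmland = 0.15, forest = 0.20, grassland = 0.15,
                  water = 0.05, builtup = 0.40, unused = 0.05),
      constraints = allow_all))
}

#' Tilt a transition matrix by scenario weights
#'
#' Off-diagonal transition probabilities into class j are scaled by the
#' scenario weight of j, then rows are renormalised. Raising one class's
#' weight therefore never decreases flow into that class, making projected
#' (and hence allocated) area monotone in the weight.
#'
#' @param matrix 6x6 row-stochastic matrix.
#' @param weights non-negative length-6 vector; at least one must be > 0.
#' @return 6x6 row-stochastic matrix.
#' @export
weight_adjusted_matrix <- function(matrix, weights) {
  if (all(weights <= 0))
    stop("validation error: at least one scenario weight must be positive",
         call. = FALSE)
  w <- weights / mean(weights)
  m <- matrix
  for (i in 1:6) {
    off <- setdiff(1:6, i)
    m[i, off] <- matrix[i, off] * w[off]
    m[i, ] <- m[i, ] / sum(m[i, ])
  }
  m
}

#' Fit per-class suitability surfaces
#'
#' Multinomial-logistic class-membership probabilities on terrain and driver
#' covariates (elevation, slope, distances to roads/rail/water, population,
#' GDP), trained on a random sample of cells of the reference map and
#' predicted for every cell. Classes with fewer than 10 training cells fall
#' back to their map frequency (with a message), and probabilities are
#' renormalised so each cell's six values sum to 1.
#'
#' @param bundle a landscape_bundle.
#' @param reference_lu categorical raster_grid used as training labels.
#' @param sample_n maximum number of training cells.
#' @param seed integer seed for the training sample.
#' @return list of 6 raster_grids (one per class) of probabilities.
#' @export
fit_suitability <- function(bundle, reference_lu, sample_n = 4000L,
                            seed = 1L) {
  feats <- cbind(
    dem = as.vector(bundle$dem$values),
    slope = as.vector(bundle$slope$values),
    dist_road = as.vector(bundle$drivers$dist_road$values),
    dist_rail = as.vector(bundle$drivers$dist_rail$values),
    dist_water = as.vector(bundle$drivers$dist_water$values),
    population = as.vector(bundle$drivers$population$values),
    gdp = as.vector(bundle$drivers$gdp$values))
  y <- as.vector(reference_lu$values)
  ok <- stats::complete.cases(feats) & !is.na(y)
  n <- sum(ok)
  if (length(unique(y[ok])) < 2L)
    stop("suitability error: need at least 2 classes present", call. = FALSE)
  # standardise; guard constant columns
  mu <- colMeans(feats[ok, , drop = FALSE])
  sdv <- apply(feats[ok, , drop = FALSE], 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  fz <- sweep(sweep(feats, 2, mu), 2, sdv, `/`)
  counts <- tabulate(y[ok], 6L)
  freq <- counts / n
  trainable <- which(counts >= 10L)
  rare <- setdiff(which(counts > 0L), trainable)
  if (length(rare))
    message("fit_suitability: class(es) ", paste(LU_NAMES[rare], collapse = ", "),
            " have < 10 cells; falling back to map frequency")
  idx <- which(ok & y %in% trainable)
  take <- with_seed(seed, {
    if (length(idx) > sample_n) sample(idx, sample_n) else idx
  })
  df <- data.frame(y = factor(y[take], levels = trainable), fz[take, ,
                                                               drop = FALSE])
  fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 300,
                        MaxNWts = 2000)
  newd <- data.frame(fz)
  pr <- stats::predict(fit, newdata = newd, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # two-class case
  full <- matrix(0, nrow(feats), 6L)
  full[, trainable] <- pr
  # rare classes keep constant frequency; rescale the fitted block
  if (length(rare)) {
    full[, trainable] <- full[, trainable] * (1 - sum(freq[rare]))
    for (r in rare) full[, r] <- freq[r]
  }
  full <- full / rowSums(full)
  nr <- nrow(reference_lu$values); nc <- ncol(reference_lu$values)
  out <- lapply(1:6, function(k)
    grid_like(reference_lu, matrix(full[, k], nr, nc)))
  names(out) <- LU_NAMES
  out
}

# summed-area-table box sum: for each cell, sum of m over the (2r+1)^2
# window clipped at the grid edge
box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr + 1L, nc + 1L)
  s[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  i <- seq_len(nr); j <- seq_len(nc)
  r1 <- pmax(i - r, 1L); r2 <- pmin(i + r, nr)
  c1 <- pmax(j - r, 1L); c2 <- pmin(j + r, nc)
  R2 <- matrix(r2 + 1L, nr, nc); R1 <- matrix(r1, nr, nc)
  C2 <- matrix(c2 + 1L, nr, nc, byrow = TRUE)
  C1 <- matrix(c1, nr, nc, byrow = TRUE)
  tot <- s[cbind(as.vector(R2), as.vector(C2))] -
    s[cbind(as.vector(R1), as.vector(C2))] -
    s[cbind(as.vector(R2), as.vector(C1))] +
    s[cbind(as.vector(R1), as.vector(C1))]
  matrix(tot, nr, nc)
}

#' Allocate projected demand onto the map by patch growing
#'
#' Iterative cellular-automata allocation: classes below their demanded area
#' claim cells from classes above theirs, along allowed transitions only.
#' Each round, candidate cells are scored by
#' suitability x (neighbourhood share + epsilon) x scenario weight, with a
#' seeded random jitter breaking ties, and the highest-scoring cells flip.
#' The neighbourhood term makes growth cling to existing patches of the
#' expanding class while the epsilon lets isolated high-suitability cells
#' found new patches. Iteration stops when every class is within `tol` of
#' its demand or no further progress is possible, in which case the
#' remaining deficit is reported in the `shortfall` attribute.
#'
#' @param start_lu categorical raster_grid.
#' @param demand named numeric length-6, target areas in km2; must total the
#'   valid map area to within one cell.
#' @param model list with `suitability` (as from [fit_suitability()]),
#'   `weights` (length 6), `constraints` (6x6 logical),
#'   `neighbourhood_radius` (cells, default 2).
#' @param seed integer; fixes the tie-break jitter.
#' @param tol relative demand tolerance per class (default 0.01).
#' @param max_iter iteration cap.
#' @return categorical raster_grid with attributes `shortfall` (signed
#'   per-class residual in cells: demanded minus allocated, so positive
#'   values are unmet demand and negative values unshed surplus) and
#'   `iterations`.
#' @export
allocate <- function(start_lu, demand, model, seed = 1L, tol = 0.01,
                     max_iter = 200L) {
  lu <- start_lu$values
  ok <- !is.na(lu)
  n <- sum(ok)
  cs <- start_lu$cell_size
  cell_km2 <- cs^2 / 1e6
  target <- round(demand / cell_km2)
  if (abs(sum(target) - n) > 1L + 1e-6)
    stop("validation error: demand total does not match map area",
         call. = FALSE)
  # absorb rounding residue into the largest class
  target[which.max(target)] <- target[which.max(target)] + (n - sum(target))
  radius <- if (is.null(model$neighbourhood_radius)) 2L
            else model$neighbourhood_radius
  w <- model$weights
  cons <- model$constraints
  suit <- lapply(model$suitability, function(g) g$values)
  jitter <- with_seed(seed,
                      matrix(stats::runif(length(lu), 0, 1e-9), nrow(lu)))
  tol_cells <- floor(tol * pmax(target, 0))
  it <- 0L
  repeat {
    it <- it + 1L
    counts <- tabulate(lu[ok], 6L)
    deficit <- as.integer(target) - counts
    if (all(abs(deficit) <= tol_cells) || it > max_iter) break
    progressed <- FALSE
    for (k in order(deficit, decreasing = TRUE)) {
      need <- deficit[k]
      if (need <= 0L) next
      donors <- which(deficit < 0L & cons[, k] & (1:6) != k)
      if (!length(donors)) next
      cand <- which(!is.na(lu) & lu %in% donors)
      if (!length(cand)) next
      nb_frac <- box_sum((!is.na(lu) & lu == k) + 0, radius) /
        pmax(box_sum(ok + 0, radius), 1)
      score <- suit[[k]][cand] * (nb_frac[cand] + 0.01) * w[k] + jitter[cand]
      ord <- cand[order(score, decreasing = TRUE)]
      # honour per-donor surplus quotas while taking the best `chunk` cells
      quota <- -deficit
      chunk <- max(1L, ceiling(need / 3))
      cls <- lu[ord]
      run <- stats::ave(rep(1L, length(ord)), cls, FUN = cumsum)
      eligible <- run <= quota[cls]
      pick <- ord[eligible][seq_len(min(chunk, sum(eligible)))]
      if (!length(pick)) next
      lu[pick] <- k
      counts <- tabulate(lu[ok], 6L)
      deficit <- as.integer(target) - counts
      progressed <- TRUE
    }
    if (!progressed) break
  }
  counts <- tabulate(lu[ok], 6L)
  # signed residual: positive = unmet demand, negative = surplus a donor
  # could not shed under the conversion constraints
  short <- as.integer(target) - counts
  names(short) <- LU_NAMES
  if (any(abs(short) > tol_cells)) {
    bad <- abs(short) > tol_cells
    warning("allocate: demand infeasible under constraints; residual of ",
            paste(sprintf("%s=%d", LU_NAMES[bad], short[bad]),
                  collapse = ", "), " cells", call. = FALSE)
  }
  out <- grid_like(start_lu, lu)
  attr(out, "shortfall") <- short
  attr(out, "iterations") <- it
  out
}

#' Class areas of a categorical map
#' @param lu categorical raster_grid.
#' @return named numeric length-6, areas in km2.
#' @export
class_areas <- function(lu) {
  counts <- tabulate(lu$values[!is.na(lu$values)], 6L)
  stats::setNames(counts * lu$cell_size^2 / 1e6, LU_NAMES)
}

#' Simulate one development scenario end to end
#'
#' Chains the full simulator: estimate the transition matrix from the last
#' two maps of the bundle's land-use series, tilt it by the scenario
#' weights, project demand `horizon_steps` Markov steps ahead, fit
#' suitability surfaces on the latest map, and allocate the demand under the
#' scenario's conversion constraints. `horizon_steps = 0` returns the
#' baseline unchanged.
#'
#' @param bundle a landscape_bundle with >= 2 land-use dates.
#' @param scenario one of "SSP126", "SSP245", "SSP585".
#' @param horizon_steps Markov steps ahead (calibration interval units;
#'   a 5-year calibration pair and a 15-year horizon give 3).
#' @param seed integer seed for suitability sampling and allocation.
#' @param suitability optional precomputed [fit_suitability()] result,
#'   reused across scenarios to save refitting.
#' @return list with `map` (raster_grid), `change_table` (data.frame),
#'   `demand`, `transition_matrix`, `scenario`.
#' @export
simulate_scenario <- function(bundle, scenario, horizon_steps = 3L,
                              seed = 1L, suitability = NULL) {
  defs <- scenario_definitions()
  if (!scenario %in% names(defs))
    stop(sprintf("validation error: unknown scenario '%s'", scenario),
         call. = FALSE)
  series <- bundle$landuse_series
  nlu <- length(series)
  if (nlu < 2L)
    stop("validation error: need >= 2 land-use dates to calibrate",
         call. = FALSE)
  baseline <- series[[nlu]]
  if (horizon_steps == 0L) {
    ct <- change_table(class_areas(baseline),
                       stats::setNames(list(class_areas(baseline)), scenario))
    return(list(map = baseline, change_table = ct,
                demand = class_areas(baseline),
                transition_matrix = diag(6), scenario = scenario))
  }
  tm <- estimate_transition_matrix(series[[nlu - 1L]], baseline)
  def <- defs[[scenario]]
  tm_w <- weight_adjusted_matrix(tm, def$weights)
  demand <- project_demand(class_areas(baseline), tm_w, horizon_steps)
  if (is.null(suitability))
    suitability <- fit_suitability(bundle, baseline, seed = seed)
  model <- list(suitability = suitability, weights = def$weights,
                constraints = def$constraints, neighbourhood_radius = 2L)
  map <- allocate(baseline, demand, model, seed = seed)
  ct <- change_table(class_areas(baseline),
                     stats::setNames(list(class_areas(map)), scenario))
  list(map = map, change_table = ct, demand = demand,
       transition_matrix = tm_w, scenario = scenario)
}

#' Map agreement: overall accuracy and Cohen's kappa
#'
#' @param simulated,observed co-registered categorical raster_grids.
#' @return list with `accuracy`, `kappa` and the 6x6 `confusion` matrix
#'   (rows = simulated, columns = observed).
#' @export
agreement_stats <- function(simulated, observed) {
  if (!same_geometry(simulated, observed))
    stop("validation error: maps are not co-registered", call. = FALSE)
  a <- simulated$values; b <- observed$values
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop("validation error: no overlapping valid cells", call. = FALSE)
  cm <- table(factor(a[ok], levels = 1:6), factor(b[ok], levels = 1:6))
  cm <- matrix(as.numeric(cm), 6, 6, dimnames = list(LU_NAMES, LU_NAMES))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) 0 else (po - pe) / (1 - pe)
  list(accuracy = po, kappa = kappa, confusion = cm)
}

#' Change table of class areas across scenarios
#'
#' `change_table()` works from per-class areas directly (e.g. a published
#' area table); `build_change_table()` measures the areas from maps first.
#' Change is scenario area minus baseline area, exactly.
#'
#' @param baseline_areas named numeric length-6 (km2).
#' @param scenario_areas named list of named numeric length-6 (km2).
#' @return data.frame with a `land_use` column, `baseline_area`, and per
#'   scenario `<name>_area` and `<name>_change` columns.
#' @export
change_table <- function(baseline_areas, scenario_areas) {
  out <- data.frame(land_use = LU_NAMES,
                    baseline_area = as.numeric(baseline_areas[LU_NAMES]))
  for (sc in names(scenario_areas)) {
    a <- as.numeric(scenario_areas[[sc]][LU_NAMES])
    out[[paste0(sc, "_area")]] <- a
    out[[paste0(sc, "_change")]] <- a - out$baseline_area
  }
  out
}

#' @rdname change_table
#' @param baseline_lu categorical raster_grid.
#' @param scenario_maps named list of categorical raster_grids.
#' @export
build_change_table <- function(baseline_lu, scenario_maps) {
  check_coregistered(c(list(baseline = baseline_lu), scenario_maps))
  change_table(class_areas(baseline_lu), lapply(scenario_maps, class_areas))
}
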