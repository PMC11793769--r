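test_that("transition matrix estimation matches hand cross-tabulation", {
  g <- function(m) raster_grid(m, 30)
  same <- g(matrix(c(1, 2, 3, 4), 2, 2))
  expect_equal(estimate_transition_matrix(same, same), diag(6),
               ignore_attr = TRUE)

  # one of two class-1 cells becomes class 2
  t1 <- g(matrix(c(1, 1, 3, 3), 2, 2))
  t2 <- g(matrix(c(1, 2, 3, 3), 2, 2))
  tm <- estimate_transition_matrix(t1, t2)
  expect_equal(tm[1, ], c(0.5, 0.5, 0, 0, 0, 0), ignore_attr = TRUE)
  # absent classes keep identity rows; all rows stochastic
  expect_equal(tm[5, 5], 1)
  expect_equal(rowSums(tm), rep(1, 6), ignore_attr = TRUE)

  nav <- g(matrix(NA_real_, 2, 2))
  expect_error(estimate_transition_matrix(nav, nav), "no overlapping")
})

test_that("demand projection is exact matrix powering with area conserved", {
  areas <- c(farmland = 100, forest = 0, grassland = 0, water = 0,
             builtup = 0, unused = 0)
  m <- diag(6); m[1, 1] <- 0.9; m[1, 2] <- 0.1
  expect_equal(project_demand(areas, m, 1),
               c(90, 10, 0, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(project_demand(areas, diag(6), 5), areas)

  set.seed(4)
  r <- matrix(runif(36), 6, 6); r <- r / rowSums(r)
  a2 <- c(10, 20, 30, 5, 5, 1)
  expect_equal(sum(project_demand(a2, r, 7)), sum(a2), tolerance = 1e-6)
  expect_error(project_demand(a2, matrix(1, 6, 6), 1), "sum to 1")
})

test_that("agreement statistics match hand-computed kappa", {
  g <- function(v) raster_grid(matrix(v, 10, 10), 30)
  a <- g(rep(1:2, each = 50))
  expect_equal(agreement_stats(a, a)$accuracy, 1)
  expect_equal(agreement_stats(a, a)$kappa, 1)

  # confusion ((40,10),(10,40)): accuracy 0.8, kappa 0.6
  sim <- g(c(rep(1, 50), rep(2, 50)))
  obs <- g(c(rep(1, 40), rep(2, 10), rep(1, 10), rep(2, 40)))
  st <- agreement_stats(sim, obs)
  expect_equal(st$accuracy, 0.8)
  expect_equal(st$kappa, 0.6)

  # a constant simulated map agrees only at chance level
  expect_equal(agreement_stats(g(rep(1, 100)), obs)$kappa, 0)
})

test_that("kappa matches a brute-force confusion-matrix oracle", {
  set.seed(8)
  for (rep in 1:3) {
    a <- matrix(sample(1:6, 64, replace = TRUE), 8, 8)
    b <- matrix(sample(1:6, 64, replace = TRUE), 8, 8)
    st <- agreement_stats(raster_grid(a, 30), raster_grid(b, 30))
    # independent double-loop confusion matrix
    cm <- matrix(0, 6, 6)
    for (i in 1:8) for (j in 1:8)
      cm[a[i, j], b[i, j]] <- cm[a[i, j], b[i, j]] + 1
    po <- sum(diag(cm)) / 64
    pe <- sum(rowSums(cm) * colSums(cm)) / 64^2
    expect_equal(st$accuracy, po, tolerance = 1e-9)
    expect_equal(st$kappa, (po - pe) / (1 - pe), tolerance = 1e-9)
  }
})

test_that("change tables are exact area differences", {
  base <- c(farmland = 100, forest = 200, grassland = 50, water = 10,
            builtup = 20, unused = 5)
  scen <- list(A = base + c(-5, 3, 0, 1, 1, 0), B = base)
  ct <- change_table(base, scen)
  expect_equal(ct$A_change, ct$A_area - ct$baseline_area)
  expect_equal(ct$B_change, rep(0, 6))
})

test_that("allocation flips exactly the demanded cells on a toy map", {
  lu <- matrix(2L, 16, 16)
  lu[1:4, 1:8] <- 1L  # 32 farmland cells in a forest matrix
  start <- raster_grid(lu, 30)
  areas <- class_areas(start)
  uniform <- lapply(1:6, function(k) raster_grid(matrix(0.5, 16, 16), 30))
  names(uniform) <- LU_NAMES
  model <- list(suitability = uniform, weights = rep(1, 6),
                constraints = matrix(TRUE, 6, 6), neighbourhood_radius = 2)

  # zero net demand: the map comes back untouched
  out0 <- allocate(start, areas, model, seed = 1)
  expect_identical(out0$values, start$values)

  # move 10 cells from farmland to built-up
  cell_km2 <- 30^2 / 1e6
  demand <- areas
  demand["farmland"] <- demand["farmland"] - 10 * cell_km2
  demand["builtup"] <- demand["builtup"] + 10 * cell_km2
  out <- allocate(start, demand, model, seed = 1)
  flips <- which(out$values != start$values)
  expect_length(flips, 10)
  expect_true(all(start$values[flips] == 1L))
  expect_true(all(out$values[flips] == 5L))
  # relabelling conserves the cell count
  expect_equal(sum(tabulate(out$values, 6)), 256)
})

test_that("raising a class's scenario weight never shrinks its demand", {
  set.seed(6)
  tm <- default_markov_drift()
  areas <- c(farmland = 1000, forest = 3000, grassland = 1200, water = 50,
             builtup = 80, unused = 10)
  w <- c(0.2, 0.3, 0.2, 0.05, 0.1, 0.05)
  prev <- -Inf
  for (wb in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    w2 <- w; w2[5] <- wb
    d <- project_demand(areas, weight_adjusted_matrix(tm, w2), 3)
    expect_gte(d[["builtup"]], prev)
    prev <- d[["builtup"]]
  }
})

test_that("suitability surfaces are proper probabilities", {
  b <- shared_bundle()
  lu <- b$landuse_series$t3
  suit <- suppressMessages(fit_suitability(b, lu, seed = 1))
  tot <- Reduce(`+`, lapply(suit, `[[`, "values"))
  expect_equal(max(abs(tot - 1)), 0, tolerance = 1e-6)
  expect_true(all(vapply(suit, function(g) all(g$values >= 0), logical(1))))
})

test_that("a perfectly separating driver yields near-perfect suitability", {
  # farmland strictly west, forest strictly east; dist_road separates them
  lu <- matrix(2L, 32, 32); lu[, 1:16] <- 1L
  sep <- matrix(rep(c(0, 5000), each = 32 * 16), 32, 32)
  b <- flat_bundle(lu)
  b$drivers$dist_road <- raster_grid(sep, 30)
  suit <- suppressMessages(fit_suitability(b, b$landuse_series$t1, seed = 2))
  pred <- ifelse(suit$farmland$values > suit$forest$values, 1L, 2L)
  expect_gt(mean(pred == lu), 0.95)
})

test_that("uninformative covariates reduce suitability to class frequency", {
  set.seed(12)
  lu <- matrix(sample(c(1L, 2L, 3L), 900, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)), 30, 30)
  b <- flat_bundle(lu)  # every covariate constant
  suit <- suppressMessages(fit_suitability(b, b$landuse_series$t1, seed = 3))
  freq <- tabulate(lu, 6) / 900
  for (k in 1:3)
    expect_equal(suit[[k]]$values[1, 1], freq[k], tolerance = 0.02)
})

test_that("scenario simulation conserves area and honours the horizon", {
  b <- shared_bundle()
  suit <- suppressMessages(fit_suitability(b, b$landuse_series$t3, seed = 5))
  sim <- suppressWarnings(
    simulate_scenario(b, "SSP585", 3, seed = 5, suitability = suit))
  base_areas <- class_areas(b$landuse_series$t3)
  expect_equal(sum(class_areas(sim$map)), sum(base_areas), tolerance = 1e-9)
  expect_equal(sim$change_table$SSP585_change,
               sim$change_table$SSP585_area - sim$change_table$baseline_area)

  # zero horizon returns the baseline untouched
  sim0 <- simulate_scenario(b, "SSP126", 0, seed = 5)
  expect_identical(sim0$map$values, b$landuse_series$t3$values)
  expect_error(simulate_scenario(b, "SSP999", 1, seed = 1),
               "unknown scenario")
})
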