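test_that("water yield reproduces closed-form Budyko limits", {
  # omega = 1, R = 1: AET/P = 2/3 so Y = P/3.
  # P = 1000, Z = 3, AWC = min(2000, 1000) * (1/3) = 333.3 -> omega = 1;
  # k_c = 1, PET = 1000 -> R = 1.
  lu <- matrix(2L, 8, 8)
  bio <- default_biophysical_table()
  bio$k_c[2] <- 1
  b <- flat_bundle(lu, precip = 1000, pet = 1000, root_depth = 1000,
                   pawc = 1 / 3)
  y <- water_yield(b, bio, z = 3, msd = 2000, landuse = b$landuse_series$t1)
  expect_equal(y$values[1, 1], 1000 / 3, tolerance = 1e-9)

  # omega = 0 (no available water): AET/P collapses to R/(1+R)
  b0 <- flat_bundle(lu, precip = 1000, pet = 700, pawc = 0)
  y0 <- water_yield(b0, bio, z = 3, landuse = b0$landuse_series$t1)
  expect_equal(y0$values[1, 1], (1 - 0.7 / 1.7) * 1000, tolerance = 1e-9)

  # zero precipitation yields zero without division blow-ups
  bz <- flat_bundle(lu, precip = 0, pet = 700)
  yz <- water_yield(bz, bio, landuse = bz$landuse_series$t1)
  expect_equal(yz$values, matrix(0, 8, 8))

  bneg <- flat_bundle(lu, precip = -5)
  expect_error(water_yield(bneg, bio, landuse = bneg$landuse_series$t1),
               "negative")
})

test_that("water yield is bounded by precipitation on a real bundle", {
  b <- shared_bundle()
  y <- water_yield(b)
  expect_true(all(y$values >= 0))
  expect_true(all(y$values <= b$precip_annual$values + 1e-9))
})

test_that("carbon storage is exact pool bookkeeping", {
  bio <- default_biophysical_table()
  bio[1, c("c_above", "c_below", "c_soil", "c_dead")] <- c(10, 5, 20, 1)
  one <- raster_grid(matrix(1L, 1, 1), 30)
  cs <- carbon_storage(one, bio)
  expect_equal(cs$total, 36 * 0.09, tolerance = 1e-12)

  zero_bio <- default_biophysical_table()
  zero_bio[, c("c_above", "c_below", "c_soil", "c_dead")] <- 0
  lu <- raster_grid(matrix(sample(1:6, 64, replace = TRUE), 8, 8), 30)
  expect_equal(carbon_storage(lu, zero_bio)$total, 0)

  # map total equals the per-class count x density x area bookkeeping
  b <- shared_bundle()
  lu3 <- b$landuse_series$t3
  cs3 <- carbon_storage(lu3)
  bio0 <- default_biophysical_table()
  dens <- rowSums(bio0[, c("c_above", "c_below", "c_soil", "c_dead")])
  counts <- tabulate(lu3$values, 6)
  expect_equal(cs3$total, sum(counts * dens * 0.09), tolerance = 1e-6)

  # converting one forest cell to built-up drops the total by the density gap
  lu_mod <- lu3
  cell <- which(lu_mod$values == 2L)[1]
  lu_mod$values[cell] <- 5L
  expect_equal(cs3$total - carbon_storage(lu_mod)$total,
               (dens[2] - dens[5]) * 0.09, tolerance = 1e-9)

  expect_error(carbon_storage(one, bio[-1, ]), "no row for class")
})

test_that("habitat degradation follows the declared decay rules", {
  # threat-free map: D identically zero
  lu <- matrix(2L, 12, 12)
  D0 <- habitat_degradation(raster_grid(lu, 30), default_threats())
  expect_equal(D0$values, matrix(0, 12, 12))

  # linear decay at half the max distance with weight 1, sensitivity 1
  lu[6, 1] <- 5L
  bio <- default_biophysical_table()
  bio$sens_builtup[2] <- 1
  th <- list(threat_spec("builtup", 5, max_dist = 300, decay = "linear",
                         weight = 1))
  D <- habitat_degradation(raster_grid(lu, 30), th, bio)
  expect_equal(D$values[6, 6], 0.5, tolerance = 1e-9)    # 150 m away
  expect_equal(D$values[6, 1], 0)                        # source itself: s=0
  # beyond max distance the threat vanishes: far corner is 376 m away
  expect_equal(D$values[12, 12], 0)

  expect_error(threat_spec("builtup", 5, 600, decay = "cubic"),
               "unknown decay")
})

test_that("habitat degradation matches an all-pairs brute-force scan", {
  set.seed(17)
  lu <- matrix(sample(c(1L, 2L, 3L, 5L), 256, replace = TRUE,
                      prob = c(0.3, 0.4, 0.2, 0.1)), 16, 16)
  th <- default_threats()
  bio <- default_biophysical_table()
  D <- habitat_degradation(raster_grid(lu, 30), th, bio)
  expect_equal(D$values, brute_degradation(lu, th, bio, 30),
               tolerance = 1e-9)
})

test_that("habitat quality obeys its closed forms and bounds", {
  lu <- raster_grid(matrix(2L, 4, 4), 30)
  bio <- default_biophysical_table()
  zeroD <- raster_grid(matrix(0, 4, 4), 30)
  expect_equal(habitat_quality(lu, zeroD, bio)$values,
               matrix(bio$habitat[2], 4, 4))

  # built-up habitat 0 stays 0 whatever the pressure
  lub <- raster_grid(matrix(5L, 4, 4), 30)
  bigD <- raster_grid(matrix(10, 4, 4), 30)
  expect_equal(habitat_quality(lub, bigD, bio)$values, matrix(0, 4, 4))

  # D^z = k^2 halves the quality (H = 1 for exactness)
  bio1 <- bio; bio1$habitat[2] <- 1
  k <- 0.3
  Dhalf <- raster_grid(matrix(k^(2 / 2.5), 4, 4), 30)
  q <- habitat_quality(lu, Dhalf, bio1, k = k, z = 2.5)
  expect_equal(q$values[1, 1], 0.5, tolerance = 1e-12)

  expect_error(habitat_quality(lu, zeroD, bio, k = -1), "k must be > 0")

  # quality strictly decreases in D wherever H > 0
  b <- shared_bundle()
  lu3 <- b$landuse_series$t3
  D <- habitat_degradation(lu3)
  q1 <- habitat_quality(lu3, D, k = 0.5)
  q2 <- habitat_quality(lu3, grid_like(D, D$values + 0.1), k = 0.5)
  H <- q1$values > 0
  expect_true(all(q2$values[H] < q1$values[H]))
  expect_true(all(q1$values >= 0 & q1$values <= 1))
})

test_that("LS factor is flat-floored and monotone in slope", {
  flat <- raster_grid(matrix(100, 6, 6), 30)
  ls0 <- ls_factor(flat)
  expect_equal(max(abs(ls0$values - ls0$values[1, 1])), 0)
  expect_equal(ls0$values[1, 1], 0)

  grads <- c(0.02, 0.05, 0.1, 0.2)
  mids <- vapply(grads, function(g) {
    dem <- raster_grid(outer(rep(0, 9), (0:8) * 30 * g, `+`), 30)
    ls_factor(dem)$values[5, 5]
  }, numeric(1))
  expect_true(all(diff(mids) > 0))
})

test_that("rainfall erosivity is the declared power law", {
  p <- raster_grid(matrix(c(0, 500, 1000, 2000), 2, 2), 30)
  r <- rainfall_erosivity(p, a = 0.03, b = 1.6)
  expect_equal(r$values[1, 1], 0)
  expect_equal(r$values, 0.03 * p$values^1.6)
  # doubling precipitation multiplies erosivity by 2^b
  r2 <- rainfall_erosivity(grid_like(p, p$values * 2), a = 0.03, b = 1.6)
  expect_equal(r2$values[2, 2], 2^1.6 * r$values[2, 2], tolerance = 1e-12)
  expect_error(rainfall_erosivity(grid_like(p, p$values - 10)), "negative")
})

test_that("soil retention is the exact factor product", {
  # ramp dem gives a known LS; constant K and R; farmland C and P
  dem_v <- outer(rep(0, 8), (0:7) * 3, `+`)
  lu <- matrix(1L, 8, 8)
  b <- flat_bundle(lu, precip = 1000, k = 0.3, dem_values = dem_v)
  ero <- raster_grid(matrix(100, 8, 8), 30)
  bio <- default_biophysical_table()
  bio$usle_c[1] <- 0.1; bio$usle_p[1] <- 0.5
  sc <- soil_retention(b, bio, erosivity = ero,
                       landuse = b$landuse_series$t1)
  ls <- ls_factor(b$dem)
  expect_equal(sc$values, 100 * 0.3 * ls$values * 0.1 * 0.5,
               tolerance = 1e-12)
  # the mid-grid hand product: LS = 2 would give SC = 3; verify scaling form
  expect_equal(100 * 0.3 * 2 * 0.1 * 0.5, 3)

  # cover factor 0 kills the product
  bio0 <- bio; bio0$usle_c[1] <- 0
  sc0 <- soil_retention(b, bio0, erosivity = ero,
                        landuse = b$landuse_series$t1)
  expect_equal(sc0$values, matrix(0, 8, 8))

  # retention variant: R*K*LS*(1 - C*P)
  alt <- soil_retention(b, bio, erosivity = ero,
                        landuse = b$landuse_series$t1, retention_form = TRUE)
  expect_equal(alt$values, 100 * 0.3 * ls$values * (1 - 0.05),
               tolerance = 1e-12)
})
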