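test_that("shipped support matrix satisfies every published marginal", {
  G <- load_support_matrix()
  m <- support_marginals(G)
  per <- m$per_es
  rownames(per) <- per$es
  expect_equal(per["habitat_quality", "n_targets"], 29)
  expect_equal(per["habitat_quality", "n_goals"], 10)
  expect_equal(per["carbon_storage", "n_targets"], 19)
  expect_equal(per["carbon_storage", "n_goals"], 7)
  expect_equal(per["water_yield", "n_targets"], 25)
  expect_equal(per["water_yield", "n_goals"], 10)
  expect_equal(per["soil_retention", "n_targets"], 9)
  expect_equal(per["soil_retention", "n_goals"], 2)
  expect_equal(m$n_goals_union, 12)
  # the CSV fixture and the in-code default agree
  expect_equal(unname(G), unname(default_support_matrix()),
               ignore_attr = TRUE)
})

test_that("degenerate support matrices are rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  G <- default_support_matrix()
  zero <- data.frame(es = rownames(G), G * 0L, check.names = FALSE)
  write.csv(zero, tmp, row.names = FALSE)
  expect_error(load_support_matrix(tmp), "all-zero")

  neg <- data.frame(es = rownames(G), G, check.names = FALSE)
  neg[1, 2] <- -1
  write.csv(neg, tmp, row.names = FALSE)
  expect_error(load_support_matrix(tmp), "non-negative integers")
})

make_panel <- function(vals, nr = 2, nc = 2) {
  p <- lapply(vals, function(v) raster_grid(matrix(v, nr, nc), 30))
  names(p) <- names(vals)
  p
}

test_that("goal scores are support-weighted means of normalised ES", {
  G <- default_support_matrix()
  ones <- make_panel(c(habitat_quality = 1, carbon_storage = 1,
                       water_yield = 1, soil_retention = 1))
  expect_equal(sdg_goal_score(ones, G, "SDG6")$values, matrix(1, 2, 2))

  # a goal supported by a single ES collapses to that ES's value
  G1 <- G * 0L
  G1["habitat_quality", "SDG1"] <- 29L
  mixed <- make_panel(c(habitat_quality = 0.4, carbon_storage = 0.9,
                        water_yield = 0.1, soil_retention = 0.7))
  expect_equal(sdg_goal_score(mixed, G1, "SDG1")$values, matrix(0.4, 2, 2))

  # scaling a column of G leaves the ratio untouched
  G3 <- G
  G3[, "SDG6"] <- G3[, "SDG6"] * 3L
  expect_equal(sdg_goal_score(mixed, G3, "SDG6")$values,
               sdg_goal_score(mixed, G, "SDG6")$values, tolerance = 1e-12)

  expect_error(sdg_goal_score(mixed, G, "SDG17"), "zero total support")
  expect_error(sdg_goal_score(mixed[-1], G, "SDG6"), "lacks ES layer")
})

test_that("goal scores match a brute-force weighted mean on a 5x5 panel", {
  set.seed(14)
  G <- default_support_matrix()
  vals <- lapply(1:4, function(i) matrix(runif(25), 5, 5))
  names(vals) <- rownames(G)
  panel <- lapply(vals, function(v) raster_grid(v, 30))
  for (goal in c("SDG2", "SDG6", "SDG15")) {
    got <- sdg_goal_score(panel, G, goal)$values
    want <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) {
      num <- 0
      for (es in rownames(G)) num <- num + vals[[es]][i, j] * G[es, goal]
      want[i, j] <- num / sum(G[, goal])
    }
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the composite averages the supported goals and is monotone", {
  g <- function(v) raster_grid(matrix(v, 2, 2), 30)
  two <- list(SDG1 = g(0.2), SDG2 = g(0.8))
  comp <- sdg_composite(two)
  expect_equal(comp$grid$values, matrix(0.5, 2, 2))
  expect_equal(comp$regional_mean, 0.5)

  same <- sdg_composite(list(a = g(0.3), b = g(0.3), c = g(0.3)))
  expect_equal(same$grid$values, matrix(0.3, 2, 2))
  expect_error(sdg_composite(list()), "empty goal set")

  # default matrix supports 12 goals, all entering the mean
  panel <- make_panel(c(habitat_quality = 0.5, carbon_storage = 0.5,
                        water_yield = 0.5, soil_retention = 0.5))
  goals <- suppressMessages(sdg_scores(panel))
  expect_length(goals, 12)
  expect_equal(sdg_composite(goals)$m, 12)

  # raising one ES cell never lowers any goal score or the composite
  set.seed(15)
  base_vals <- c(habitat_quality = 0.4, carbon_storage = 0.6,
                 water_yield = 0.3, soil_retention = 0.7)
  p1 <- make_panel(base_vals)
  p2 <- p1
  p2$water_yield$values[1, 1] <- 0.9
  g1 <- suppressMessages(sdg_scores(p1))
  g2 <- suppressMessages(sdg_scores(p2))
  for (nm in names(g1))
    expect_true(all(g2[[nm]]$values >= g1[[nm]]$values - 1e-12))
  expect_gte(sdg_composite(g2)$regional_mean, sdg_composite(g1)$regional_mean)
})
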