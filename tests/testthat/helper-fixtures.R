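# Shared fixtures, built once per test run.

# memoised 64x64 synthetic bundle used by several suites
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_bundle(generator_config(seed = 42, nrow = 64,
                                                 ncol = 64), n_dates = 3)
    cache
  }
})

# a minimal bundle with hand-set layers, for closed-form checks
flat_bundle <- function(lu, precip = 1000, pet = 1000, root_depth = 1000,
                        pawc = 1 / 3, k = 0.3, cell_size = 30,
                        dem_values = NULL) {
  nr <- nrow(lu); nc <- ncol(lu)
  const <- function(v) raster_grid(matrix(v, nr, nc), cell_size)
  as_grid <- function(v) if (is.matrix(v)) raster_grid(v, cell_size)
                         else const(v)
  dem <- if (is.null(dem_values)) const(500) else raster_grid(dem_values,
                                                              cell_size)
  list(landuse_series = list(t1 = raster_grid(lu, cell_size)),
       dem = dem,
       slope = slope_from_dem(dem),
       precip_annual = as_grid(precip),
       pet_annual = as_grid(pet),
       erodibility_k = as_grid(k),
       root_depth = as_grid(root_depth),
       pawc = as_grid(pawc),
       drivers = list(dist_road = const(100), dist_rail = const(100),
                      dist_water = const(100), population = const(50),
                      gdp = const(50)))
}

# independent brute-force global Moran's I (binary queen weights, no NA)
brute_morans_i <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m - mean(m)
  num <- 0; s0 <- 0
  for (i1 in 1:nr) for (j1 in 1:nc) for (i2 in 1:nr) for (j2 in 1:nc) {
    if (i1 == i2 && j1 == j2) next
    if (abs(i1 - i2) <= 1 && abs(j1 - j2) <= 1) {
      num <- num + z[i1, j1] * z[i2, j2]
      s0 <- s0 + 1
    }
  }
  n <- nr * nc
  (n / s0) * num / sum(z^2)
}

# independent brute-force Gi* z-scores (binary queen + self, no NA)
brute_gi_star <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  n <- nr * nc
  xb <- mean(m)
  S <- sqrt(sum((m - xb)^2) / n)
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    w <- 0; wx <- 0
    for (i2 in max(1, i - 1):min(nr, i + 1))
      for (j2 in max(1, j - 1):min(nc, j + 1)) {
        w <- w + 1
        wx <- wx + m[i2, j2]
      }
    num <- wx - xb * w
    den <- S * sqrt((n * w - w^2) / (n - 1))
    out[i, j] <- num / den
  }
  out
}

# independent brute-force habitat degradation (all-pairs distance scan)
brute_degradation <- function(lu, threats, biophys, cell_size) {
  nr <- nrow(lu); nc <- ncol(lu)
  D <- matrix(0, nr, nc)
  for (th in threats) {
    src <- which(lu == th$source_class, arr.ind = TRUE)
    if (nrow(src) == 0) next
    sens_by_class <- biophys[[paste0("sens_", th$name)]][order(biophys$class)]
    for (i in 1:nr) for (j in 1:nc) {
      d <- min(sqrt((src[, 1] - i)^2 + (src[, 2] - j)^2)) * cell_size
      dec <- if (d > th$max_dist) 0
             else if (th$decay == "linear") 1 - d / th$max_dist
             else exp(-2.99 * d / th$max_dist)
      D[i, j] <- D[i, j] + th$weight * max(dec, 0) * sens_by_class[lu[i, j]]
    }
  }
  D
}

# independent entropy-weight derivation on a plain matrix (cells x indicators)
brute_entropy_weights <- function(x) {
  n <- nrow(x)
  e <- apply(x, 2, function(col) {
    p <- col / sum(col)
    p <- p[p > 0]
    -sum(p * log(p)) / log(n)
  })
  (1 - e) / sum(1 - e)
}
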