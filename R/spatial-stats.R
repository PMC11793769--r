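#' Spatial weights on the raster lattice
#'
#' Binary contiguity weights described by a set of integer cell offsets.
#' `"queen"` (the default) links each cell to its 8 surrounding cells;
#' `"distance_band"` links all cells whose centre-to-centre distance is at
#' most `band` metres. Edge cells keep their reduced neighbour sets (no
#' wrap-around).
#'
#' @param scheme `"queen"` or `"distance_band"`.
#' @param band band distance in metres (required for `"distance_band"`).
#' @param cell_size metres per cell, used to convert the band to cells.
#' @return object of class `spatial_weights` holding the offset list.
#' @export
spatial_weights <- function(scheme = c("queen", "distance_band"),
                            band = NULL, cell_size = 30) {
  scheme <- match.arg(scheme)
  if (scheme == "queen") {
    off <- expand.grid(dr = -1:1, dc = -1:1)
    off <- off[!(off$dr == 0 & off$dc == 0), ]
  } else {
    if (is.null(band) || band <= 0)
      stop("validation error: distance_band needs a positive band",
           call. = FALSE)
    r <- floor(band / cell_size)
    off <- expand.grid(dr = -r:r, dc = -r:r)
    keep <- (off$dr^2 + off$dc^2) * cell_size^2 <= band^2 &
      !(off$dr == 0 & off$dc == 0)
    off <- off[keep, ]
    if (nrow(off) == 0L)
      stop("validation error: band smaller than one cell", call. = FALSE)
  }
  structure(list(scheme = scheme, offsets = as.matrix(off)),
            class = "spatial_weights")
}

# sum of m over each cell's neighbours (NA treated as 0); m must be numeric
neighbour_sum <- function(m, offsets) {
  nr <- nrow(m); nc <- ncol(m)
  m0 <- m; m0[is.na(m0)] <- 0
  acc <- matrix(0, nr, nc)
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets[i, 1L]; dc <- offsets[i, 2L]
    sr <- max(1L, 1L - dr):min(nr, nr - dr)
    sc <- max(1L, 1L - dc):min(nc, nc - dc)
    acc[sr, sc] <- acc[sr, sc] + m0[sr + dr, sc + dc]
  }
  acc
}

#' Global Moran's I
#'
#' Spatial autocorrelation of a raster layer under binary contiguity
#' weights, with the analytical expectation `E[I] = -1/(n-1)` and a
#' normality-based z-score and two-sided p-value.
#'
#' @param grid a raster_grid.
#' @param weights a [spatial_weights()] object.
#' @return list with `I`, `expected`, `z`, `p`, `n`.
#' @export
morans_i <- function(grid, weights = spatial_weights("queen")) {
  x <- grid$values
  ok <- is.finite(x)
  n <- sum(ok)
  if (n < 9L)
    stop("validation error: need >= 9 valid cells", call. = FALSE)
  xb <- mean(x[ok])
  z <- x - xb
  z[!ok] <- NA
  if (sum(z[ok]^2) < 1e-300)
    stop("validation error: zero-variance grid, Moran's I undefined",
         call. = FALSE)
  off <- weights$offsets
  nbz <- neighbour_sum(z, off)          # sum of neighbouring deviations
  deg <- neighbour_sum(ok + 0, off)     # valid-neighbour counts
  s0 <- sum(deg[ok])
  num <- sum(z[ok] * nbz[ok])
  I <- (n / s0) * num / sum(z[ok]^2)
  eI <- -1 / (n - 1)
  # normality-assumption variance; weights symmetric binary
  s1 <- 2 * s0
  s2 <- sum((2 * deg[ok])^2)
  varI <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - eI^2
  zs <- (I - eI) / sqrt(varI)
  list(I = I, expected = eI, z = zs, p = 2 * stats::pnorm(-abs(zs)), n = n)
}

#' Getis-Ord Gi* hot/cold-spot statistic
#'
#' Per-cell z-score
#' `(sum_j w_ij x_j - Xbar W_i) / (S sqrt((n W2_i - W_i^2)/(n - 1)))`
#' with binary weights that include the focal cell (the Gi* convention),
#' `Xbar` the global mean, `S` the population standard deviation, `W_i` the
#' weight sum and `W2_i` the sum of squared weights at cell i. Scores are
#' classified into the seven confidence codes of [classify_confidence()].
#'
#' @param grid a raster_grid.
#' @param weights a [spatial_weights()] object (self-inclusion is handled
#'   internally).
#' @return list of class `hotspot_map` with raster_grids `z` and `classes`
#'   plus `n`.
#' @export
getis_ord_gi_star <- function(grid, weights = spatial_weights("queen")) {
  x <- grid$values
  ok <- is.finite(x)
  n <- sum(ok)
  if (n < 9L)
    stop("validation error: need >= 9 valid cells", call. = FALSE)
  xb <- mean(x[ok])
  S <- sqrt(sum((x[ok] - xb)^2) / n)
  off <- weights$offsets
  wx <- neighbour_sum(x, off) + ifelse(ok, x, 0)     # include self
  wi <- neighbour_sum(ok + 0, off) + (ok + 0)
  if (S < 1e-300) {
    warning("getis_ord_gi_star: constant grid; all z set to 0",
            call. = FALSE)
    zmat <- matrix(0, nrow(x), ncol(x))
    zmat[!ok] <- NA
    zg <- grid_like(grid, zmat)
    return(structure(list(z = zg, classes = classify_confidence(zg), n = n),
                     class = "hotspot_map"))
  }
  num <- wx - xb * wi
  den <- S * sqrt(pmax(n * wi - wi^2, 0) / (n - 1))
  zmat <- ifelse(den > 0, num / den, 0)
  zmat[!ok] <- NA
  zg <- grid_like(grid, zmat)
  structure(list(z = zg, classes = classify_confidence(zg), n = n),
            class = "hotspot_map")
}

#' Classify z-scores into confidence-coded hot/cold-spot classes
#'
#' Codes -3..3: sign(z) times the confidence level reached by |z| against
#' the two-sided normal critical values 1.645 (90%), 1.960 (95%) and
#' 2.576 (99%). 0 means not significant.
#'
#' @param z_grid raster_grid (or numeric matrix/vector) of z-scores.
#' @return same shape as the input, integer codes -3..3.
#' @export
classify_confidence <- function(z_grid) {
  cls <- function(z) {
    lev <- (abs(z) >= 1.645) + (abs(z) >= 1.960) + (abs(z) >= 2.576)
    as.integer(sign(z) * lev)
  }
  if (is_raster_grid(z_grid)) {
    v <- z_grid$values
    out <- matrix(NA_integer_, nrow(v), ncol(v))
    ok <- is.finite(v)
    out[ok] <- cls(v[ok])
    grid_like(z_grid, out)
  } else cls(z_grid)
}
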