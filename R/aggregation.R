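#' Min-max normalisation of a raster layer
#'
#' `(x - min) / (max - min)` over valid cells, mapping the layer onto
#' [0, 1]. A constant layer carries no ordering information; by the
#' package's declared convention it maps to 0.5 everywhere, with a warning,
#' so downstream weighted sums stay defined.
#'
#' @param grid a raster_grid.
#' @return raster_grid with values in [0, 1].
#' @export
minmax_normalize <- function(grid) {
  v <- grid$values
  ok <- is.finite(v)
  if (!any(ok))
    stop("validation error: no valid cells to normalise", call. = FALSE)
  lo <- min(v[ok]); hi <- max(v[ok])
  if (hi - lo < 1e-300) {
    warning("minmax_normalize: constant layer mapped to 0.5 by convention",
            call. = FALSE)
    v[ok] <- 0.5
    return(grid_like(grid, v))
  }
  grid_like(grid, (v - lo) / (hi - lo))
}

#' Entropy weights for a panel of indicator layers
#'
#' Information-entropy weighting over valid cells: each indicator's values
#' are turned into shares `p_ij = x_ij / sum_i(x_ij)`, its entropy is
#' `e_j = -(1/ln n) sum p ln p` (with `0 ln 0 := 0`), and the weight is the
#' normalised redundancy `w_j = (1 - e_j) / sum_k(1 - e_k)`. Indicators
#' with more spatial dispersion get more weight. Expects non-negative
#' (typically min-max normalised) layers. If every indicator is constant,
#' weights fall back to uniform with a warning.
#'
#' @param panel named list of co-registered raster_grids.
#' @return named numeric vector of weights summing to 1.
#' @export
entropy_weights <- function(panel) {
  if (length(panel) < 2L)
    stop("validation error: need >= 2 indicators", call. = FALSE)
  check_coregistered(panel)
  ok <- Reduce(`&`, lapply(panel, function(g) is.finite(g$values)))
  n <- sum(ok)
  if (n < 2L)
    stop("validation error: need >= 2 valid cells", call. = FALSE)
  ent <- vapply(panel, function(g) {
    x <- g$values[ok]
    if (any(x < 0))
      stop("validation error: entropy weights need non-negative indicators",
           call. = FALSE)
    s <- sum(x)
    if (s <= 0) return(1)           # no information: maximal entropy
    p <- x / s
    p <- p[p > 0]
    -sum(p * log(p)) / log(n)
  }, numeric(1))
  d <- 1 - ent
  if (all(d < 1e-12)) {
    warning("entropy_weights: all indicators constant; uniform weights",
            call. = FALSE)
    d <- rep(1, length(panel))
  }
  w <- d / sum(d)
  names(w) <- names(panel)
  w
}

#' Weighted total ecosystem-service surface
#'
#' Per-cell weighted sum of normalised indicator layers. With weights
#' summing to 1 and layers in [0, 1] the total is in [0, 1].
#'
#' @param panel named list of normalised raster_grids.
#' @param weights named numeric vector; names must match the panel.
#' @return raster_grid of the weighted total.
#' @export
total_es <- function(panel, weights) {
  miss <- setdiff(names(panel), names(weights))
  if (length(miss))
    stop("validation error: no weight for layer(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  check_coregistered(panel)
  acc <- 0
  for (nm in names(panel)) acc <- acc + weights[[nm]] * panel[[nm]]$values
  grid_like(panel[[1L]], acc)
}

#' Normalise a raw ES panel
#'
#' Applies [minmax_normalize()] to each layer of a raw ecosystem-service
#' panel, the form consumed by [entropy_weights()], [total_es()] and the
#' SDG scoring.
#'
#' @param panel named list of raster_grids in raw units.
#' @return named list of raster_grids in [0, 1].
#' @export
normalize_panel <- function(panel) lapply(panel, minmax_normalize)
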