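#' Raster grid objects
#'
#' A `raster_grid` is the universal currency of the pipeline: a single-band
#' planar raster stored as a numeric matrix (row 1 = northern edge) with a
#' cell size in metres, the (x, y) of the upper-left corner, and `NA` marking
#' nodata cells. There is no CRS: the grid is abstract planar, and any
#' projection metadata in input files is carried through I/O untouched and
#' never used in computation.
#'
#' @param values numeric or integer matrix; `NA` = nodata.
#' @param cell_size side length of a square cell in metres (> 0).
#' @param origin numeric length-2, (x, y) of the upper-left corner.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 30, origin = c(0, 0)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster_grid: dimensions must be positive", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("raster_grid: cell_size must be a single positive number",
         call. = FALSE)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, cell_size %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  ok <- is.finite(v)
  if (any(ok))
    cat(sprintf("  valid cells: %d, range [%g, %g]\n",
                sum(ok), min(v[ok]), max(v[ok])))
  else
    cat("  all cells nodata\n")
  invisible(x)
}

#' @rdname raster_grid
#' @param x object to test.
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Grid geometry helpers
#'
#' `same_geometry()` tests whether two grids are co-registered (identical
#' dimensions, cell size and origin). `check_coregistered()` raises an error
#' naming the offending layer when any grid in a list disagrees with the
#' first.
#'
#' @param a,b raster_grid objects.
#' @return `same_geometry` a logical; `check_coregistered` invisibly TRUE.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' @rdname same_geometry
#' @param grids named list of raster_grid objects.
#' @export
check_coregistered <- function(grids) {
  stopifnot(length(grids) >= 1L)
  ref <- grids[[1L]]
  nms <- names(grids)
  if (is.null(nms)) nms <- as.character(seq_along(grids))
  for (i in seq_along(grids)) {
    if (!same_geometry(ref, grids[[i]]))
      stop(sprintf("co-registration error: layer '%s' disagrees with '%s' %s",
                   nms[i], nms[1L],
                   "(dimensions, cell size and origin must all match)"),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a new grid with the same geometry as a template
#' @param template raster_grid supplying geometry.
#' @param values matrix of the same dimensions (defaults to template values).
#' @export
grid_like <- function(template, values = template$values) {
  if (!identical(dim(values), dim(template$values)))
    stop("grid_like: values dimensions must match template", call. = FALSE)
  raster_grid(values, template$cell_size, template$origin)
}

#' Read and write Esri ASCII grids
#'
#' The package's raster interchange format is the Esri ASCII grid (`.asc`):
#' plain text, readable by any GIS, with the grid geometry (corner, cell
#' size, nodata value) carried in the six-line header. Integer-valued layers
#' (e.g. land-use classes) round-trip bit-exactly; floats to full printed
#' precision.
#'
#' @param grid a raster_grid.
#' @param path file path ending in `.asc`.
#' @param nodata value written for `NA` cells (default -9999).
#' @param digits significant digits for floating layers.
#' @return `write_ascii_grid` the path invisibly; `read_ascii_grid` a
#'   raster_grid.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999, digits = 10) {
  v <- grid$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", grid$origin[1]),
    sprintf("yllcorner %.6f", grid$origin[2] - nrow(v) * grid$cell_size),
    sprintf("cellsize %.6f", grid$cell_size),
    sprintf("NODATA_value %g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  ln <- readLines(path, n = 6L)
  kv <- strsplit(trimws(ln), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  for (need in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (!need %in% key)
      stop(sprintf("read_ascii_grid: missing header field '%s'", need),
           call. = FALSE)
  nodata <- if ("nodata_value" %in% key) val[["nodata_value"]] else -9999
  dat <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(val[["nrows"]]); nc <- as.integer(val[["ncols"]])
  if (length(dat) != nr * nc)
    stop("read_ascii_grid: body size does not match header dimensions",
         call. = FALSE)
  m <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  origin <- c(val[["xllcorner"]], val[["yllcorner"]] + nr * val[["cellsize"]])
  raster_grid(m, val[["cellsize"]], origin)
}

#' Slope from a DEM
#'
#' Horn's eight-neighbour finite-difference slope (the method used by common
#' GIS slope tools), in degrees. Edge cells use replicated borders.
#'
#' @param dem raster_grid of elevations in metres.
#' @return raster_grid of slope in degrees, non-negative.
#' @export
slope_from_dem <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  # replicate borders so edge cells get a one-sided estimate
  zp <- z[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  at <- function(dr, dc) zp[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc]
  h <- dem$cell_size
  # Horn 1981 weights; x east, y north (row index grows southwards)
  dzdx <- ((at(-1L, 1L) + 2 * at(0L, 1L) + at(1L, 1L)) -
           (at(-1L, -1L) + 2 * at(0L, -1L) + at(1L, -1L))) / (8 * h)
  dzdy <- ((at(-1L, -1L) + 2 * at(-1L, 0L) + at(-1L, 1L)) -
           (at(1L, -1L) + 2 * at(1L, 0L) + at(1L, 1L))) / (8 * h)
  grid_like(dem, atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi)
}

#' Euclidean distance to the nearest marked cell
#'
#' Distance transform in metres from every cell to the nearest `TRUE` cell of
#' `mask`, computed with an exact Euclidean distance map. Cells on a feature
#' get 0. If the mask has no `TRUE` cell, every distance is `Inf`.
#'
#' @param mask logical matrix marking feature cells.
#' @param cell_size metres per cell side.
#' @return numeric matrix of distances in metres.
#' @export
distance_to_cells <- function(mask, cell_size) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  # distmap gives each non-zero pixel its distance to the nearest zero pixel
  img <- matrix(1, nrow(mask), ncol(mask))
  img[mask] <- 0
  d <- EBImage::distmap(img, metric = "euclidean")
  as.matrix(d) * cell_size
}
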