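# Regular-grid raster containers and plain-text raster I/O.
#
# Grids are planar (meters), row 1 is the bottom row; pixel centers sit at
# x0 + (col - 0.5) * pixel, y0 + (row - 0.5) * pixel. Rasters are written as
# ESRI ASCII grids (one band per file) with a JSON manifest for stacks.

#' Define a regular raster grid
#'
#' @param x0,y0 Coordinates of the lower-left grid corner (meters).
#' @param nrow,ncol Grid dimensions.
#' @param pixel Pixel edge length in meters.
#' @return An object of class `gs_grid`.
#' @export
gs_grid <- function(x0, y0, nrow, ncol, pixel) {
  stopifnot(pixel > 0, nrow >= 1, ncol >= 1)
  structure(list(x0 = x0, y0 = y0, nrow = as.integer(nrow),
                 ncol = as.integer(ncol), pixel = pixel),
            class = "gs_grid")
}

grid_equal <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$x0 - b$x0) < tol && abs(a$y0 - b$y0) < tol && abs(a$pixel - b$pixel) < tol
}

#' Pixel-center coordinates of a grid
#'
#' @param grid A `gs_grid`.
#' @return List with vectors `x` (length ncol) and `y` (length nrow).
#' @export
pixel_centers <- function(grid) {
  list(
    x = grid$x0 + (seq_len(grid$ncol) - 0.5) * grid$pixel,
    y = grid$y0 + (seq_len(grid$nrow) - 0.5) * grid$pixel
  )
}

#' Rasterize a geometry to a pixel-center mask
#'
#' A pixel belongs to the mask iff its center lies inside the geometry —
#' the same inclusion rule used by zonal extraction.
#'
#' @param grid A `gs_grid`.
#' @param geom A `gs_geom`.
#' @return Logical matrix `nrow x ncol` (row 1 = bottom row).
#' @export
raster_mask <- function(grid, geom) {
  mask <- matrix(FALSE, nrow = grid$nrow, ncol = grid$ncol)
  if (gs_is_empty(geom)) return(mask)
  ctr <- pixel_centers(grid)
  bb <- gs_bbox(geom)
  cols <- which(ctr$x >= bb[1] & ctr$x <= bb[3])
  rows <- which(ctr$y >= bb[2] & ctr$y <= bb[4])
  if (!length(cols) || !length(rows)) return(mask)
  px <- rep(ctr$x[cols], times = length(rows))
  py <- rep(ctr$y[rows], each = length(cols))
  inside <- gs_contains(geom, px, py)
  mask[rows, cols] <- matrix(inside, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  mask
}

#' Construct an NDVI stack
#'
#' @param grid A `gs_grid`.
#' @param values Numeric array `nrow x ncol x T` of NDVI percent values
#'   (0-100); NA marks nodata.
#' @param periods Ordered period labels (length T).
#' @return An object of class `ndvi_stack`.
#' @export
ndvi_stack <- function(grid, values, periods = NULL) {
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == grid$nrow, dim(values)[2] == grid$ncol)
  nt <- dim(values)[3]
  if (nt < 4) stop("an NDVI stack needs at least 4 periods")
  if (is.null(periods)) periods <- sprintf("p%02d", seq_len(nt))
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 100) stop("NDVI values must lie in [0, 100]")
  structure(list(grid = grid, values = values, periods = periods),
            class = "ndvi_stack")
}

#' @export
print.ndvi_stack <- function(x, ...) {
  cat(sprintf("<ndvi_stack: %d x %d pixels (%g m), %d periods>\n",
              x$grid$nrow, x$grid$ncol, x$grid$pixel, length(x$periods)))
  invisible(x)
}

#' Write a single raster band as an ESRI ASCII grid
#'
#' @param values Numeric matrix `nrow x ncol` (row 1 = bottom row).
#' @param grid A `gs_grid`.
#' @param path Output file path.
#' @param nodata Sentinel written for NA cells.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(nrow(values) == grid$nrow, ncol(values) == grid$ncol)
  hdr <- c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.10g", grid$x0),
    sprintf("yllcorner %.10g", grid$y0),
    sprintf("cellsize %.10g", grid$pixel),
    sprintf("NODATA_value %g", nodata)
  )
  v <- values[rev(seq_len(grid$nrow)), , drop = FALSE]  # top row first on disk
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 15), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()].
#' @return List with elements `grid` (a `gs_grid`) and `values` (matrix,
#'   row 1 = bottom row, NA for nodata).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(i) strsplit(trimws(hdr[i]), "\\s+")[[1]][2]
  ncols <- as.integer(val(1)); nrows <- as.integer(val(2))
  x0 <- as.numeric(val(3)); y0 <- as.numeric(val(4))
  cell <- as.numeric(val(5)); nodata <- as.numeric(val(6))
  body <- lines[-(1:6)]
  v <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  stopifnot(nrow(v) == nrows, ncol(v) == ncols)
  v[v == nodata] <- NA_real_
  list(grid = gs_grid(x0, y0, nrows, ncols, cell),
       values = v[rev(seq_len(nrows)), , drop = FALSE])
}

#' Write an NDVI stack as band files plus a manifest
#'
#' One ASCII grid per period (`band_01.asc`, ...) and a `manifest.json`
#' recording periods, band files, and grid metadata.
#'
#' @param stack An `ndvi_stack`.
#' @param dir Output directory (created if absent).
#' @export
write_ndvi_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nt <- length(stack$periods)
  files <- sprintf("band_%02d.asc", seq_len(nt))
  for (t in seq_len(nt)) {
    write_ascii_grid(stack$values[, , t], stack$grid, file.path(dir, files[t]))
  }
  manifest <- list(format = "ndvi_stack/1", periods = stack$periods, bands = files,
                   pixel_size_m = stack$grid$pixel)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an NDVI stack written by [write_ndvi_stack()]
#'
#' @param dir Directory containing `manifest.json` and band files.
#' @return An `ndvi_stack`.
#' @export
read_ndvi_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  bands <- lapply(manifest$bands, function(f) read_ascii_grid(file.path(dir, f)))
  grid <- bands[[1]]$grid
  vals <- array(NA_real_, dim = c(grid$nrow, grid$ncol, length(bands)))
  for (t in seq_along(bands)) {
    stopifnot(grid_equal(grid, bands[[t]]$grid))
    vals[, , t] <- bands[[t]]$values
  }
  ndvi_stack(grid, vals, periods = manifest$periods)
}
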