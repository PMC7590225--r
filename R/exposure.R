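# Zonal extraction of greenness metrics within boundary geometries.
#
# The inclusion rule is pixel-center-in-polygon: a pixel contributes to a
# zone iff its center lies inside the zone geometry; partial pixels are not
# area-weighted. Aggregation to the county is a single zonal mean over the
# county's (clipped, possibly buffered) boundary geometry, never a mean of
# sub-polygon means. Nodata pixels are excluded; a zone capturing no pixel
# center yields a missing value.

#' Zonal mean of a raster band within a geometry
#'
#' @param values Numeric matrix `nrow x ncol` (row 1 = bottom row).
#' @param grid The `gs_grid` the band lives on.
#' @param geom A `gs_geom` in the same coordinate system.
#' @return Mean of non-nodata pixels whose centers fall inside the geometry,
#'   or NA if no pixel qualifies (empty geometries log a diagnostic).
#' @export
zonal_mean <- function(values, grid, geom) {
  if (gs_is_empty(geom)) {
    message("zonal_mean: empty geometry, returning NA")
    return(NA_real_)
  }
  mask <- raster_mask(grid, geom)
  v <- values[mask]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Assemble the county exposure table
#'
#' One record per county x scheme x buffer x metric. Buffers are applied to
#' each scheme's clipped county geometries; metric values come from the
#' greenness raster's MXN and TIN bands. Counties whose geometry is empty
#' under a scheme receive missing values (and are dropped listwise by the
#' downstream models under that scheme).
#'
#' @param greenness A `greenness_raster`.
#' @param boundaries List of `boundary_set` objects (typically the six
#'   schemes at buffer 0).
#' @param buffers Numeric vector of buffer distances in meters to evaluate
#'   (applied on top of each boundary's own buffer state, which must be 0
#'   when extra buffers are requested).
#' @return An `exposure_table`: tidy tibble with columns `county_id`,
#'   `scheme`, `buffer_m`, `metric` ("MXN"/"TIN"), `value`, carrying
#'   provenance attributes.
#' @export
build_exposure_table <- function(greenness, boundaries, buffers = 0) {
  stopifnot(inherits(greenness, "greenness_raster"))
  grid <- greenness$grid
  r_county <- character(0); r_scheme <- character(0)
  r_buffer <- numeric(0); r_metric <- character(0); r_value <- numeric(0)
  for (b in boundaries) {
    stopifnot(inherits(b, "boundary_set"))
    if (length(buffers) > 1 || any(buffers != b$buffer_m)) {
      stopifnot(b$buffer_m == 0)
    }
    for (buf in buffers) {
      bb <- if (buf == b$buffer_m) b else apply_buffer(b, buf)
      ids <- names(bb$geoms)
      mxn <- rep(NA_real_, length(ids)); tin <- rep(NA_real_, length(ids))
      for (k in seq_along(ids)) {
        g <- bb$geoms[[k]]
        if (gs_is_empty(g)) next
        mask <- raster_mask(grid, g)
        vm <- greenness$mxn[mask]; vt <- greenness$tin[mask]
        vm <- vm[!is.na(vm)]; vt <- vt[!is.na(vt)]
        if (length(vm)) mxn[k] <- mean(vm)
        if (length(vt)) tin[k] <- mean(vt)
      }
      r_county <- c(r_county, ids, ids)
      r_scheme <- c(r_scheme, rep(b$scheme, 2 * length(ids)))
      r_buffer <- c(r_buffer, rep(buf, 2 * length(ids)))
      r_metric <- c(r_metric, rep(c("MXN", "TIN"), each = length(ids)))
      r_value <- c(r_value, mxn, tin)
    }
  }
  out <- tibble::tibble(
    county_id = r_county, scheme = r_scheme, buffer_m = r_buffer,
    metric = r_metric, value = r_value
  )
  if (anyDuplicated(out[, c("county_id", "scheme", "buffer_m", "metric")])) {
    stop("duplicate (county, scheme, buffer, metric) records")
  }
  class(out) <- c("exposure_table", class(out))
  attr(out, "provenance") <- list(
    schemes = vapply(boundaries, `[[`, character(1), "scheme"),
    buffers = buffers
  )
  out
}

as_exposure_df <- function(exposure) {
  stopifnot(all(c("county_id", "scheme", "buffer_m", "metric", "value") %in% names(exposure)))
  exposure
}

#' Widen an exposure table to one column per scheme/metric/buffer
#'
#' Columns are named like `tin_combined` (buffer 0) or `tin_combined_b500`,
#' matching the wide layout used by the regression grids.
#'
#' @param exposure An `exposure_table`.
#' @return Tibble with one row per county.
#' @export
exposure_wide <- function(exposure) {
  df <- tibble::as_tibble(as_exposure_df(exposure))
  df$col <- paste0(tolower(df$metric), "_", df$scheme,
                   ifelse(df$buffer_m == 0, "", paste0("_b", df$buffer_m)))
  tidyr::pivot_wider(df[, c("county_id", "col", "value")],
                     names_from = "col", values_from = "value")
}
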