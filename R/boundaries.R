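# Community-activity-space boundary schemes.
#
# Six schemes delineate the area whose greenness counts as a county's
# community green space: the whole county; block groups above a residential
# density threshold (1 household/ha and 1 household/10 ha); census places;
# urban areas; and the union of places and urban areas. Each scheme can be
# buffered by 0/300/500/1000 m. Boundary geometries are clipped to their
# county before exposure extraction; buffers are applied afterwards and may
# cross county lines, with exposure still attributed to the owning county.

BOUNDARY_SCHEMES <- c("county", "h1ha", "h10ha", "place", "urban_area", "combined")
BUFFER_SIZES <- c(0, 300, 500, 1000)

#' Select block groups meeting a residential-density threshold
#'
#' Density is households per hectare. The area entering the density is taken
#' from the geometry whenever it disagrees with the stored `area_ha` field by
#' more than 1% (the geometry is authoritative); records with non-positive
#' area are rejected with a diagnostic.
#'
#' @param blockgroups Block-group tibble with columns `households`, `area_ha`
#'   and rectangle bounds `xmin`, `ymin`, `xmax`, `ymax`.
#' @param min_density Minimum households per hectare (1.0 for the 1 H/1 HA
#'   scheme, 0.1 for 1 H/10 HAs).
#' @return The subset of rows with density >= `min_density`.
#' @export
select_residential_blockgroups <- function(blockgroups, min_density) {
  stopifnot(min_density > 0)
  geom_ha <- (blockgroups$xmax - blockgroups$xmin) *
    (blockgroups$ymax - blockgroups$ymin) / 1e4
  area <- blockgroups$area_ha
  mismatch <- is.finite(geom_ha) & geom_ha > 0 &
    abs(geom_ha - area) / geom_ha > 0.01
  if (any(mismatch)) {
    message(sum(mismatch), " block group(s) had stored areas >1% off the geometry; using geometric area")
    area[mismatch] <- geom_ha[mismatch]
  }
  bad <- !(is.finite(area) & area > 0)
  if (any(bad)) {
    warning(sum(bad), " block group(s) rejected for non-positive area")
    blockgroups <- blockgroups[!bad, , drop = FALSE]
    area <- area[!bad]
  }
  density <- blockgroups$households / area
  blockgroups[density >= min_density, , drop = FALSE]
}

new_boundary_set <- function(scheme, geoms, buffer_m = 0, provenance = scheme) {
  structure(list(scheme = scheme, buffer_m = buffer_m, geoms = geoms,
                 clipped_to_county = (buffer_m == 0), provenance = provenance),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  n_empty <- sum(vapply(x$geoms, gs_is_empty, logical(1)))
  cat(sprintf("<boundary_set '%s', buffer %g m: %d counties (%d empty)>\n",
              x$scheme, x$buffer_m, length(x$geoms), n_empty))
  invisible(x)
}

#' Build one boundary scheme for every county
#'
#' @param world A `synthetic_world`.
#' @param scheme One of `county`, `h1ha`, `h10ha`, `place`, `urban_area`,
#'   `combined`.
#' @return A `boundary_set` holding one (possibly empty) clipped geometry per
#'   county. Counties with no qualifying area (for example no urban area) get
#'   an empty geometry and are later dropped listwise under that scheme.
#' @export
build_boundary <- function(world, scheme) {
  scheme <- match.arg(scheme, BOUNDARY_SCHEMES)
  ids <- world$counties$id
  geoms <- stats::setNames(vector("list", length(ids)), ids)
  if (scheme == "county") {
    for (id in ids) geoms[[id]] <- county_geom(world, id)
  } else if (scheme %in% c("h1ha", "h10ha")) {
    min_density <- if (scheme == "h1ha") 1.0 else 0.1
    sel <- select_residential_blockgroups(world$blockgroups, min_density)
    for (id in ids) {
      rows <- sel[sel$county_id == id, , drop = FALSE]
      geoms[[id]] <- if (nrow(rows) == 0) gs_empty() else gs_dissolve(
        gs_rects_geom(cbind(rows$xmin, rows$ymin, rows$xmax, rows$ymax))
      )
    }
  } else if (scheme %in% c("place", "urban_area")) {
    layer <- if (scheme == "place") world$places else world$urban_areas
    for (id in ids) {
      g <- layer[[id]]
      geoms[[id]] <- if (is.null(g) || gs_is_empty(g)) gs_empty() else
        gs_dissolve(gs_clip_rect(g, county_rect(world, id)))
    }
  } else { # combined = place union urban_area
    for (id in ids) {
      parts <- c(
        if (!is.null(world$places[[id]])) world$places[[id]]$parts else list(),
        if (!is.null(world$urban_areas[[id]])) world$urban_areas[[id]]$parts else list()
      )
      geoms[[id]] <- if (!length(parts)) gs_empty() else
        gs_dissolve(gs_clip_rect(gs_geom(parts), county_rect(world, id)))
    }
  }
  new_boundary_set(scheme, geoms)
}

#' Buffer every county geometry of a boundary set
#'
#' @param boundary A `boundary_set`.
#' @param buffer_m Euclidean buffer in meters (>= 0); 0 returns the input
#'   unchanged.
#' @param quad_segs Arc discretization per quarter circle (>= 16).
#' @return A `boundary_set` with buffered geometries.
#' @export
apply_buffer <- function(boundary, buffer_m, quad_segs = 16) {
  stopifnot(inherits(boundary, "boundary_set"))
  if (buffer_m < 0) stop("buffer_m must be non-negative")
  if (buffer_m == 0) return(boundary)
  geoms <- lapply(boundary$geoms, gs_buffer, buffer_m = buffer_m, quad_segs = quad_segs)
  out <- new_boundary_set(boundary$scheme, geoms, buffer_m = buffer_m,
                          provenance = paste0(boundary$provenance, "+buffer", buffer_m))
  out$clipped_to_county <- FALSE
  out
}

county_union_area <- function(geoms_per_county, res = 50) {
  total <- 0
  for (g in geoms_per_county) {
    if (gs_is_empty(g)) next
    total <- total + gs_area(g, res = res)
  }
  total
}

pair_intersection_area <- function(ga, gb, county_rect, res = 50) {
  if (gs_is_empty(ga) || gs_is_empty(gb)) return(0)
  ra <- gs_rect_matrix(ga); rb <- gs_rect_matrix(gb)
  if (!is.null(ra) && !is.null(rb)) {
    return(klee_area(rect_intersect_lists(ra, rb)))
  }
  bb <- county_rect
  xs <- seq(bb[1] + res / 2, bb[3], by = res)
  ys <- seq(bb[2] + res / 2, bb[4], by = res)
  px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
  sum(gs_contains(ga, px, py) & gs_contains(gb, px, py)) * res^2
}

#' Coverage accounting across boundary schemes
#'
#' Reports, for each scheme and for the union of all schemes, the absolute
#' area and the percent of the total region area, plus the pairwise overlap
#' fractions area(i intersect j) / area(i). Areas are exact for unbuffered
#' (rectangle-based) geometries and lattice-sampled otherwise.
#'
#' @param boundaries List of `boundary_set` objects sharing one world.
#' @param world The `synthetic_world` they were built from.
#' @param res Sampling resolution in meters for non-rectangular geometries.
#' @return List with `schemes` (tibble: scheme, area_m2, pct_of_region),
#'   `union` (area and percent of the union of all schemes), and `overlap`
#'   (row-normalized pairwise overlap fraction matrix).
#' @export
coverage_stats <- function(boundaries, world, res = 50) {
  region_area <- sum((world$counties$xmax - world$counties$xmin) *
                     (world$counties$ymax - world$counties$ymin))
  names(boundaries) <- vapply(boundaries, `[[`, character(1), "scheme")
  areas <- vapply(boundaries, function(b) county_union_area(b$geoms, res = res), numeric(1))

  ids <- world$counties$id
  union_area <- 0
  for (id in ids) {
    parts <- list()
    all_rect <- TRUE
    for (b in boundaries) {
      g <- b$geoms[[id]]
      if (is.null(g) || gs_is_empty(g)) next
      parts <- c(parts, g$parts)
      if (is.null(gs_rect_matrix(g))) all_rect <- FALSE
    }
    if (!length(parts)) next
    g_all <- gs_geom(parts)
    union_area <- union_area + if (all_rect) klee_area(gs_rect_matrix(g_all)) else
      gs_area(g_all, res = res)
  }

  k <- length(boundaries)
  overlap <- matrix(NA_real_, k, k, dimnames = list(names(boundaries), names(boundaries)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    inter <- 0
    for (id in ids) {
      inter <- inter + pair_intersection_area(
        boundaries[[i]]$geoms[[id]], boundaries[[j]]$geoms[[id]],
        county_rect(world, id), res = res
      )
    }
    overlap[i, j] <- if (areas[i] > 0) inter / areas[i] else NA_real_
  }

  list(
    schemes = tibble::tibble(scheme = names(boundaries), area_m2 = unname(areas),
                             pct_of_region = 100 * unname(areas) / region_area),
    union = tibble::tibble(area_m2 = union_area,
                           pct_of_region = 100 * union_area / region_area),
    overlap = overlap
  )
}
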