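# Plain-text interchange: GeoJSON vector layers and JSON configs.
#
# Coordinates are planar meters (no geodesy); the files carry a `crs_note`
# property documenting that convention. Rectangular parts survive a
# write/read round trip bit-for-bit in structure (the reader re-detects
# axis-aligned rectangles so exact containment predicates are preserved).

geom_to_coords <- function(g) {
  lapply(g$parts, function(p) {
    ring <- rbind(p$xy, p$xy[1, , drop = FALSE])  # close the ring
    list(unname(split(ring, row(ring))) |> lapply(unname))
  })
}

coords_to_geom <- function(coords, disjoint = FALSE) {
  parts <- lapply(coords, function(poly) {
    ring <- do.call(rbind, lapply(poly[[1]], function(v) c(v[[1]], v[[2]])))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    if (nrow(ring) == 4) {
      xs <- sort(unique(ring[, 1])); ys <- sort(unique(ring[, 2]))
      if (length(xs) == 2 && length(ys) == 2) {
        return(gs_rect(xs[1], ys[1], xs[2], ys[2]))
      }
    }
    gs_poly_part(ring)
  })
  gs_geom(parts, disjoint = disjoint)
}

#' Write features to GeoJSON
#'
#' @param features List of features, each `list(id, properties, geometry)`
#'   with a `gs_geom` geometry.
#' @param path Output path.
#' @export
write_geojson <- function(features, path) {
  fc <- list(
    type = "FeatureCollection",
    crs_note = "planar Cartesian meters",
    features = lapply(features, function(f) {
      list(
        type = "Feature",
        id = f$id,
        properties = c(f$properties, list(disjoint = isTRUE(f$geometry$disjoint))),
        geometry = list(type = "MultiPolygon", coordinates = geom_to_coords(f$geometry))
      )
    })
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read features from GeoJSON written by [write_geojson()]
#'
#' @param path GeoJSON file path.
#' @return List of features, each `list(id, properties, geometry)`.
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(fc$features, function(f) {
    props <- f$properties
    disjoint <- isTRUE(props$disjoint)
    props$disjoint <- NULL
    list(
      id = f$id,
      properties = props,
      geometry = coords_to_geom(f$geometry$coordinates, disjoint = disjoint)
    )
  })
}

#' Write a world config as structured JSON
#'
#' Every key of [world_config()] is written; reading re-validates through
#' the constructor so unset keys fall back to documented defaults.
#'
#' @param config A `world_config`.
#' @param path Output path.
#' @export
write_world_config <- function(config, path) {
  raw <- unclass(config)
  # named numeric vectors would serialize as bare arrays; keep the names
  raw$household_density <- lapply(raw$household_density, as.list)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a world config written by [write_world_config()]
#' @param path JSON file path.
#' @return A validated `world_config`.
#' @export
read_world_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$household_density <- lapply(raw$household_density, function(v) unlist(v))
  raw$ndvi_params <- as.data.frame(raw$ndvi_params)
  # JSON reads whole numbers back as integers; restore double storage so a
  # round-tripped config regenerates bit-identical worlds
  dbl <- c("urban_fraction", "county_size_m", "pixel_size_m", "county_amp_range",
           "county_season_shift", "noise_sd", "effect_beta_tin_on_exercise",
           "beta_tin_physical", "beta_tin_mental", "health_noise_sd", "town_prob")
  for (nm in intersect(dbl, names(raw))) raw[[nm]] <- as.numeric(raw[[nm]])
  for (cl in setdiff(names(raw$ndvi_params), "class")) {
    raw$ndvi_params[[cl]] <- as.numeric(raw$ndvi_params[[cl]])
  }
  do.call(world_config, raw)
}

#' Write the synthetic world's layers to a directory
#'
#' Counties, block groups, places and urban areas as GeoJSON; land cover as
#' an ESRI ASCII grid of class indices (with a JSON legend); the config as
#' JSON.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cf <- world$counties
  write_geojson(lapply(seq_len(nrow(cf)), function(i) list(
    id = cf$id[i],
    properties = list(urban = cf$urban[i], population = cf$population[i]),
    geometry = gs_geom(list(gs_rect(cf$xmin[i], cf$ymin[i], cf$xmax[i], cf$ymax[i])),
                       disjoint = TRUE)
  )), file.path(dir, "counties.geojson"))
  bg <- world$blockgroups
  write_geojson(lapply(seq_len(nrow(bg)), function(i) list(
    id = bg$id[i],
    properties = list(county_id = bg$county_id[i], label = bg$label[i],
                      households = bg$households[i], area_ha = bg$area_ha[i]),
    geometry = gs_geom(list(gs_rect(bg$xmin[i], bg$ymin[i], bg$xmax[i], bg$ymax[i])),
                       disjoint = TRUE)
  )), file.path(dir, "blockgroups.geojson"))
  for (layer in c("places", "urban_areas")) {
    geoms <- world[[layer]]
    keep <- names(geoms)[!vapply(geoms, gs_is_empty, logical(1))]
    write_geojson(lapply(keep, function(id) list(
      id = paste0(layer, "_", id),
      properties = list(county_id = id),
      geometry = geoms[[id]]
    )), file.path(dir, paste0(layer, ".geojson")))
  }
  write_ascii_grid(world$landcover$classes, world$landcover$grid,
                   file.path(dir, "landcover.asc"))
  jsonlite::write_json(list(classes = world$landcover$levels),
                       file.path(dir, "landcover_legend.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_world_config(world$config, file.path(dir, "config.json"))
  invisible(dir)
}
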