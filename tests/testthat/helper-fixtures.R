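# Small fixed configurations used across tests. Worlds are regenerated from
# these configs at test time; nothing is stored on disk.

tiny_config <- function(seed = 1, ...) {
  world_config(
    n_counties = 6, urban_fraction = 1 / 3,
    blockgroups_per_county = 4, county_size_m = 2000,
    pixel_size_m = 250, seed = seed, ...
  )
}

small_config <- function(seed = 1, ...) {
  world_config(
    n_counties = 12, urban_fraction = 0.25,
    blockgroups_per_county = 16, county_size_m = 3000,
    pixel_size_m = 250, seed = seed, ...
  )
}

# brute-force zonal mean: enumerate every pixel center, point-in-geometry
brute_zonal <- function(values, grid, geom) {
  ctr <- pixel_centers(grid)
  total <- 0; count <- 0
  for (r in seq_len(grid$nrow)) for (c in seq_len(grid$ncol)) {
    if (is.na(values[r, c])) next
    if (gs_contains(geom, ctr$x[c], ctr$y[r])) {
      total <- total + values[r, c]; count <- count + 1
    }
  }
  if (count == 0) NA_real_ else total / count
}
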