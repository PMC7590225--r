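# Boundary schemes, residential-density selection, buffers, coverage.

test_that("density thresholds include and exclude by simple arithmetic", {
  bg <- tibble::tibble(
    id = c("a", "b"), county_id = "c1",
    households = c(50, 0), area_ha = c(100, 50),
    xmin = c(0, 1000), ymin = 0, xmax = c(1000, 2000), ymax = 1000
  )
  bg$xmax <- bg$xmin + 1000; bg$ymax <- 1000
  bg$area_ha <- c(100, 100)  # matches the 1000 x 1000 m geometry
  expect_equal(nrow(select_residential_blockgroups(bg, 1.0)), 0)   # density 0.5 and 0
  expect_equal(select_residential_blockgroups(bg, 0.1)$id, "a")
  expect_equal(nrow(select_residential_blockgroups(bg, 1e-9)), 1)  # zero households never qualify
})

test_that("selection equals a brute-force filter on a random fixture", {
  set.seed(19)
  n <- 200
  bg <- tibble::tibble(
    id = sprintf("bg%03d", 1:n), county_id = "c1",
    xmin = 0, ymin = 0, xmax = 1000, ymax = 1000,
    area_ha = 100, households = rpois(n, 60)
  )
  for (thr in c(1.0, 0.1, 0.6)) {
    got <- select_residential_blockgroups(bg, thr)$id
    want <- bg$id[bg$households / bg$area_ha >= thr]
    expect_identical(got, want)
  }
})

test_that("geometry overrides a stored area that disagrees by more than 1%", {
  bg <- tibble::tibble(
    id = "a", county_id = "c1", households = 90,
    xmin = 0, ymin = 0, xmax = 1000, ymax = 1000,
    area_ha = 50  # stored density 1.8; geometric density 0.9
  )
  expect_message(got <- select_residential_blockgroups(bg, 1.0), "geometric area")
  expect_equal(nrow(got), 0)
})

test_that("non-positive areas are rejected with a diagnostic", {
  bg <- tibble::tibble(
    id = c("good", "bad"), county_id = "c1", households = c(200, 200),
    xmin = 0, ymin = 0, xmax = 1000, ymax = 1000, area_ha = c(100, 100)
  )
  # break the geometry and stored area of the bad record
  bg$xmax[2] <- bg$xmin[2]
  bg$area_ha[2] <- 0
  expect_warning(got <- select_residential_blockgroups(bg, 1.0), "non-positive")
  expect_identical(got$id, "good")
})

test_that("the 1H/1HA boundary is a geometric subset of 1H/10HAs in every county", {
  w <- generate_region(small_config(seed = 21))
  b1 <- build_boundary(w, "h1ha")
  b10 <- build_boundary(w, "h10ha")
  for (cid in w$counties$id) {
    g1 <- b1$geoms[[cid]]; g10 <- b10$geoms[[cid]]
    if (gs_is_empty(g1)) next
    a1 <- gs_area(g1)
    inter <- klee_area(communitygreen:::rect_intersect_lists(
      communitygreen:::gs_rect_matrix(g1), communitygreen:::gs_rect_matrix(g10)))
    expect_equal(inter, a1, tolerance = 1e-9)
  }
})

test_that("the county scheme reproduces the county layer and combined dominates its parts", {
  w <- generate_region(small_config(seed = 22))
  bc <- build_boundary(w, "county")
  for (cid in w$counties$id) {
    expect_equal(gs_area(bc$geoms[[cid]]),
                 (w$counties$xmax[w$counties$id == cid] - w$counties$xmin[w$counties$id == cid])^2)
  }
  bp <- build_boundary(w, "place")
  bu <- build_boundary(w, "urban_area")
  bpu <- build_boundary(w, "combined")
  for (cid in w$counties$id) {
    expect_gte(gs_area(bpu$geoms[[cid]]) + 1e-9,
               max(gs_area(bp$geoms[[cid]]), gs_area(bu$geoms[[cid]])))
  }
  expect_error(build_boundary(w, "voronoi"))
})

test_that("buffers grow areas monotonically and buffer 0 is the identity", {
  w <- generate_region(tiny_config(seed = 23))
  b <- build_boundary(w, "combined")
  expect_identical(apply_buffer(b, 0), b)
  areas <- sapply(c(300, 500, 1000), function(buf) {
    bb <- apply_buffer(b, buf)
    vapply(bb$geoms, gs_area, numeric(1), res = 25)
  })
  for (i in seq_len(nrow(areas))) {
    expect_true(all(diff(areas[i, ]) >= 0))
  }
})

test_that("coverage accounting matches a 50 m rasterization oracle", {
  w <- generate_region(tiny_config(seed = 24))
  schemes <- c("county", "h1ha", "h10ha", "place", "urban_area", "combined")
  bs <- lapply(schemes, function(s) build_boundary(w, s))
  cov <- coverage_stats(bs, w)
  expect_equal(cov$schemes$pct_of_region[cov$schemes$scheme == "county"], 100, tolerance = 1e-9)
  expect_true(all(cov$union$pct_of_region + 1e-9 >= cov$schemes$pct_of_region))
  # independent oracle: rasterize each scheme at 50 m pixel centers
  bb <- c(0, 0, max(w$counties$xmax), max(w$counties$ymax))
  oracle_grid <- gs_grid(0, 0, (bb[4] - bb[2]) / 50, (bb[3] - bb[1]) / 50, 50)
  region_area <- sum((w$counties$xmax - w$counties$xmin) * (w$counties$ymax - w$counties$ymin))
  for (k in seq_along(bs)) {
    mask <- matrix(FALSE, oracle_grid$nrow, oracle_grid$ncol)
    for (g in bs[[k]]$geoms) if (!gs_is_empty(g)) mask <- mask | raster_mask(oracle_grid, g)
    oracle_pct <- 100 * sum(mask) * 50^2 / region_area
    expect_lt(abs(cov$schemes$pct_of_region[k] - oracle_pct), 1)
  }
  # overlap fractions: county scheme contains every other scheme entirely
  expect_true(all(abs(cov$overlap[, "county"] - 1) < 1e-9, na.rm = TRUE))
  expect_true(all(cov$overlap >= -1e-9 & cov$overlap <= 1 + 1e-9, na.rm = TRUE))
})

test_that("counties without urban areas get empty geometries, not errors", {
  w <- generate_region(world_config(n_counties = 30, urban_fraction = 0.2,
                                    county_size_m = 3000, town_prob = 0.5, seed = 25))
  bu <- build_boundary(w, "urban_area")
  n_empty <- sum(vapply(bu$geoms, gs_is_empty, logical(1)))
  expect_gt(n_empty, 0)
  gr <- compute_greenness(generate_ndvi_stack(w, w$config))
  ex <- build_exposure_table(gr, list(bu))
  expect_equal(sum(is.na(ex$value)), 2 * n_empty)
})
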