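# Zonal extraction and the exposure table.

test_that("a uniform raster yields its value for any covering geometry", {
  grid <- gs_grid(0, 0, 8, 8, 100)
  vals <- matrix(55, 8, 8)
  expect_equal(zonal_mean(vals, grid, gs_geom(list(gs_rect(120, 130, 480, 470)))), 55)
  expect_equal(zonal_mean(vals, grid, gs_geom(list(gs_rect(0, 0, 800, 800)))), 55)
})

test_that("a rectangle covering exactly four pixels averages them", {
  grid <- gs_grid(0, 0, 2, 2, 100)
  vals <- matrix(c(1, 3, 2, 4), 2, 2)  # values 1..4
  expect_equal(zonal_mean(vals, grid, gs_geom(list(gs_rect(0, 0, 200, 200)))), 2.5)
  # covering only the bottom row
  expect_equal(zonal_mean(vals, grid, gs_geom(list(gs_rect(0, 0, 200, 100)))),
               mean(vals[1, ]))
})

test_that("zonal means equal the pixel-enumeration oracle on random polygons", {
  set.seed(31)
  grid <- gs_grid(0, 0, 48, 64, 50)
  vals <- matrix(runif(48 * 64, 0, 100), 48, 64)
  vals[sample(length(vals), 100)] <- NA
  for (trial in 1:40) {
    kind <- sample(c("rect", "tri", "multi", "buffered"), 1)
    geom <- switch(kind,
      rect = {
        x0 <- runif(1, 0, 2500); y0 <- runif(1, 0, 1900)
        gs_geom(list(gs_rect(x0, y0, x0 + runif(1, 100, 700), y0 + runif(1, 100, 700))))
      },
      tri = {
        x0 <- runif(1, 200, 2500); y0 <- runif(1, 200, 1900)
        gs_geom(list(communitygreen:::gs_poly_part(
          cbind(c(x0, x0 + 600, x0), c(y0, y0, y0 + 500))
        )))
      },
      multi = gs_rects_geom(rbind(
        c(100, 100, 700, 600), c(500, 400, 1300, 900)
      )),
      buffered = gs_buffer(gs_geom(list(gs_rect(800, 800, 1300, 1200))), 220)
    )
    expect_equal(zonal_mean(vals, grid, geom), brute_zonal(vals, grid, geom))
  }
})

test_that("zonal means are invariant to vertex order and multipart splitting", {
  grid <- gs_grid(0, 0, 20, 20, 50)
  vals <- matrix(seq_len(400), 20, 20)
  tri <- cbind(c(100, 800, 100), c(100, 100, 700))
  g_ccw <- gs_geom(list(communitygreen:::gs_poly_part(tri)))
  g_cw <- gs_geom(list(communitygreen:::gs_poly_part(tri[3:1, ])))
  expect_equal(zonal_mean(vals, grid, g_ccw), zonal_mean(vals, grid, g_cw))

  whole <- gs_geom(list(gs_rect(0, 0, 600, 400)))
  halves <- gs_rects_geom(rbind(c(0, 0, 300, 400), c(300, 0, 600, 400)), disjoint = TRUE)
  expect_equal(zonal_mean(vals, grid, whole), zonal_mean(vals, grid, halves))
})

test_that("county means are pixel-count-weighted means of any partition", {
  grid <- gs_grid(0, 0, 16, 16, 250)
  vals <- matrix(runif(256, 0, 100), 16, 16)
  whole <- gs_geom(list(gs_rect(0, 0, 4000, 4000)))
  parts <- list(
    gs_geom(list(gs_rect(0, 0, 4000, 1000))),
    gs_geom(list(gs_rect(0, 1000, 4000, 2500))),
    gs_geom(list(gs_rect(0, 2500, 4000, 4000)))
  )
  means <- vapply(parts, function(p) zonal_mean(vals, grid, p), numeric(1))
  counts <- vapply(parts, function(p) sum(raster_mask(grid, p)), numeric(1))
  expect_equal(zonal_mean(vals, grid, whole),
               sum(means * counts) / sum(counts), tolerance = 1e-9)
})

test_that("empty geometries yield missing values with a diagnostic", {
  grid <- gs_grid(0, 0, 4, 4, 100)
  vals <- matrix(1, 4, 4)
  expect_message(v <- zonal_mean(vals, grid, gs_geom(list())), "empty")
  expect_true(is.na(v))
  # a non-empty geometry capturing no pixel center is missing too
  expect_true(is.na(suppressMessages(
    zonal_mean(vals, grid, gs_geom(list(gs_rect(10, 10, 40, 40)))))))
})

test_that("a fully covered county carries twelve green-space values", {
  cfg <- tiny_config(seed = 33)
  w <- generate_region(cfg)
  gr <- compute_greenness(generate_ndvi_stack(w, cfg))
  schemes <- c("county", "h1ha", "h10ha", "place", "urban_area", "combined")
  bs <- lapply(schemes, function(s) build_boundary(w, s))
  ex <- build_exposure_table(gr, bs)
  expect_equal(nrow(ex), 6 * 2 * nrow(w$counties))
  counts <- table(ex$county_id[!is.na(ex$value)])
  full <- names(counts)[counts == 12]
  expect_gt(length(full), 0)
  # the county-scheme TIN equals the county-wide zonal mean of the tin band
  cid <- w$counties$id[1]
  got <- ex$value[ex$county_id == cid & ex$scheme == "county" & ex$metric == "TIN"]
  expect_equal(got, zonal_mean(gr$tin, gr$grid, county_geom(w, cid)))
})

test_that("the wide exposure layout names scheme/metric/buffer columns", {
  cfg <- tiny_config(seed = 34)
  w <- generate_region(cfg)
  gr <- compute_greenness(generate_ndvi_stack(w, cfg))
  b <- build_boundary(w, "combined")
  ex <- build_exposure_table(gr, list(b), buffers = c(0, 300))
  wde <- exposure_wide(ex)
  expect_true(all(c("tin_combined", "mxn_combined", "tin_combined_b300") %in% names(wde)))
  expect_equal(nrow(wde), nrow(w$counties))
})
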