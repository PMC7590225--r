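# Synthetic world generator: determinism, tiling, planted-effect recovery.

test_that("identical configs give byte-identical worlds, stacks and tables", {
  cfg <- tiny_config(seed = 1)
  w1 <- generate_region(cfg)
  w2 <- generate_region(cfg)
  expect_identical(w1, w2)
  s1 <- generate_ndvi_stack(w1, cfg)
  s2 <- generate_ndvi_stack(w2, cfg)
  expect_identical(s1, s2)
  gr <- compute_greenness(s1)
  ex <- build_exposure_table(gr, list(build_boundary(w1, "combined")))
  h1 <- generate_health(w1, ex, cfg)
  h2 <- generate_health(w2, ex, cfg)
  expect_identical(h1, h2)
  # a different seed changes the world
  expect_false(identical(w1, generate_region(tiny_config(seed = 2))))
})

test_that("the urban fraction fixes the exact urban county count", {
  w <- generate_region(tiny_config(seed = 3))
  expect_equal(sum(w$counties$urban), 2)  # 6 counties at fraction 1/3
  w2 <- generate_region(small_config(seed = 3))
  expect_equal(sum(w2$counties$urban), 3)  # 12 at 0.25
})

test_that("block groups tile their county exactly", {
  w <- generate_region(small_config(seed = 5))
  for (cid in w$counties$id) {
    bg <- w$blockgroups[w$blockgroups$county_id == cid, ]
    county_area <- (w$counties$xmax[w$counties$id == cid] - w$counties$xmin[w$counties$id == cid]) *
      (w$counties$ymax[w$counties$id == cid] - w$counties$ymin[w$counties$id == cid])
    tile_area <- sum((bg$xmax - bg$xmin) * (bg$ymax - bg$ymin))
    expect_lt(abs(tile_area - county_area) / county_area, 1e-6)
    # pairwise interior-disjoint: the union area equals the summed area
    union_area <- klee_area(cbind(bg$xmin, bg$ymin, bg$xmax, bg$ymax))
    expect_lt(abs(union_area - county_area) / county_area, 1e-6)
  }
  expect_true(all(w$blockgroups$households >= 0))
})

test_that("places and urban areas lie inside their county", {
  w <- generate_region(small_config(seed = 6))
  for (cid in w$counties$id) {
    cr <- communitygreen:::county_rect(w, cid)
    for (layer in list(w$places[[cid]], w$urban_areas[[cid]])) {
      for (p in layer$parts) {
        expect_true(p$rect[1] >= cr[1] - 1e-9 && p$rect[3] <= cr[3] + 1e-9 &&
                    p$rect[2] >= cr[2] - 1e-9 && p$rect[4] <= cr[4] + 1e-9)
      }
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(world_config(n_counties = 1), "n_counties")
  expect_error(world_config(blockgroups_per_county = 5), "perfect square")
  expect_error(world_config(blockgroups_per_county = 0))
  expect_error(world_config(county_size_m = 1000, pixel_size_m = 250,
                            blockgroups_per_county = 64), "cannot host")
  expect_error(world_config(periods_per_year = 3), "periods_per_year")
})

test_that("NDVI values stay in [0, 100] under noise", {
  cfg <- tiny_config(seed = 7, noise_sd = 10)
  st <- generate_ndvi_stack(generate_region(cfg), cfg)
  expect_true(all(st$values >= 0 & st$values <= 100))
})

test_that("health percentages stay in [0, 100] and the truth sidecar matches config", {
  cfg <- small_config(seed = 8, effect_beta_tin_on_exercise = 0.8)
  sim <- simulate_study(cfg)
  tab <- sim$health$table
  num <- vapply(tab, is.numeric, logical(1))
  expect_true(all(as.matrix(tab[, num]) >= 0 & as.matrix(tab[, num]) <= 100))
  expect_equal(sim$health$truth$beta_tin_exercise, 0.8)
  expect_equal(unname(sim$health$truth$coefs$exercise[["tin"]]), 0.8)
  expect_identical(sim$health$truth$effect_scheme, "combined")
})

test_that("with zero noise OLS recovers the planted coefficients exactly", {
  cfg <- experiment_config(n_counties = 40, seed = 9, health_noise_sd = 0)
  sim <- simulate_study(cfg)
  fit <- suppressWarnings(communitygreen:::fit_generating_model(sim, "combined"))
  truth <- sim$health$truth$coefs$exercise
  got <- fit$coefficients
  expect_equal(got$B[got$term == "greenspace"], unname(truth[["tin"]]), tolerance = 1e-8)
  for (nm in setdiff(names(truth), "tin")) {
    expect_equal(got$B[got$term == nm], unname(truth[[nm]]), tolerance = 1e-8)
  }
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("the planted effect is recovered without bias across replicate worlds", {
  rec <- recovery_experiment(40, experiment_config(seed = 1), seed = 500)
  mc_se <- sd(rec$estimate) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$estimate) - 0.8), 3 * mc_se)
})
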