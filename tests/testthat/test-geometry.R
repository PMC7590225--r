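# Planar geometry kernel: areas, buffers, clipping, containment.

test_that("buffered square area matches the closed-form Minkowski sum", {
  a <- 1000
  sq <- gs_geom(list(gs_rect(0, 0, a, a)), disjoint = TRUE)
  for (b in c(300, 500, 1000)) {
    buf <- gs_buffer(sq, b)
    expected <- a^2 + 4 * a * b + pi * b^2
    expect_lt(abs(gs_area(buf) - expected) / expected, 0.005)
  }
})

test_that("buffering by zero is the identity and negative buffers error", {
  g <- gs_geom(list(gs_rect(0, 0, 500, 300), gs_rect(700, 0, 900, 200)), disjoint = TRUE)
  expect_identical(gs_buffer(g, 0), g)
  expect_error(gs_buffer(g, -10), "non-negative")
})

test_that("buffer containment uses the exact Minkowski sum of rectangles", {
  g <- gs_geom(list(gs_rect(0, 0, 100, 100)))
  buf <- gs_buffer(g, 50)
  # corner diagonal: inside at distance < 50 from the corner, outside beyond
  expect_true(gs_contains(buf, -30, -30))   # sqrt(1800) ~ 42.4 < 50
  expect_false(gs_contains(buf, -40, -40))  # sqrt(3200) ~ 56.6 > 50
  expect_true(gs_contains(buf, 150, 50))    # edge offset exactly at 50
  expect_false(gs_contains(buf, 151, 50))
})

test_that("union area of rectangles equals a unit-cell enumeration oracle", {
  set.seed(7)
  for (trial in 1:10) {
    n <- sample(2:8, 1)
    rects <- t(replicate(n, {
      x0 <- sample(0:20, 1); y0 <- sample(0:20, 1)
      c(x0, y0, x0 + sample(1:10, 1), y0 + sample(1:10, 1))
    }))
    # oracle: count covered 1x1 cells on the integer lattice
    covered <- matrix(FALSE, 40, 40)
    for (i in seq_len(n)) {
      covered[(rects[i, 2] + 1):rects[i, 4], (rects[i, 1] + 1):rects[i, 3]] <- TRUE
    }
    expect_equal(klee_area(rects), sum(covered))
    g <- gs_rects_geom(rects)
    expect_equal(gs_area(g), sum(covered))
  }
})

test_that("dissolving decomposes rectangle unions into disjoint parts, idempotently", {
  g <- gs_rects_geom(rbind(c(0, 0, 10, 10), c(5, 5, 15, 15), c(20, 0, 25, 5)))
  d1 <- gs_dissolve(g)
  expect_true(d1$disjoint)
  expect_equal(gs_area(d1), klee_area(gs_rect_matrix(g)))
  d2 <- gs_dissolve(d1)
  expect_equal(gs_area(d2), gs_area(d1))
  # parts are pairwise interior-disjoint: total part area equals union area
  expect_equal(sum(vapply(d1$parts, communitygreen:::part_area, numeric(1))), gs_area(d1))
})

test_that("point-in-polygon agrees with the rectangle predicate and half-plane checks", {
  set.seed(11)
  px <- runif(500, -2, 12); py <- runif(500, -2, 12)
  rect_poly <- communitygreen:::gs_poly_part(cbind(c(2, 9, 9, 2), c(1, 1, 7, 7)))
  got <- communitygreen:::point_in_poly(px, py, rect_poly$xy)
  want <- px > 2 & px < 9 & py > 1 & py < 7
  # boundary points are excluded from the comparison (either rule is fine there)
  off_boundary <- abs(px - 2) > 1e-9 & abs(px - 9) > 1e-9 & abs(py - 1) > 1e-9 & abs(py - 7) > 1e-9
  expect_identical(got[off_boundary], want[off_boundary])

  # right triangle (0,0)-(10,0)-(0,10): inside iff x>0, y>0, x+y<10
  tri <- cbind(c(0, 10, 0), c(0, 0, 10))
  got <- communitygreen:::point_in_poly(px, py, tri)
  want <- px > 0 & py > 0 & (px + py) < 10
  off <- abs(px + py - 10) > 1e-9 & px > 1e-9 & py > 1e-9
  expect_identical(got[off], want[off])
})

test_that("clipping to a rectangle preserves the intersection area", {
  g <- gs_geom(list(gs_rect(0, 0, 10, 10)))
  clipped <- gs_clip_rect(g, c(5, 5, 20, 20))
  expect_equal(gs_area(clipped), 25)
  # convex polygon clip: triangle cut by a window
  tri <- gs_geom(list(communitygreen:::gs_poly_part(cbind(c(0, 10, 0), c(0, 0, 10)))))
  half <- gs_clip_rect(tri, c(0, 0, 5, 10))
  expect_equal(gs_area(half), 50 - 12.5)  # remove the right triangle beyond x = 5
  # clip fully outside drops the part
  expect_true(gs_is_empty(gs_clip_rect(g, c(100, 100, 110, 110))))
})

test_that("lattice-sampled areas preserve subset ordering for nested buffers", {
  g <- gs_rects_geom(rbind(c(0, 0, 800, 500), c(1200, 0, 1500, 900)))
  areas <- vapply(c(300, 500, 1000), function(b) gs_area(gs_buffer(g, b), res = 20), numeric(1))
  expect_true(all(diff(areas) > 0))
})
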