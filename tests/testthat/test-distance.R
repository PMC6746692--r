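test_that("speed cost map follows q = eps_D + beta_G |grad z|^2", {
  flat <- matrix(0.4, 6, 6)
  expect_true(all(speed_cost_map(flat) == 1e-3))
  expect_true(all(speed_cost_map(flat, beta_G = 0) == 1e-3))
  # |grad z| = 0.1 with defaults -> 10.001
  expect_equal(1e-3 + 1000 * 0.1^2, 10.001)
  z <- toy_image()
  q <- speed_cost_map(z, 1e-3, 1000)
  expect_equal(q, 1e-3 + 1000 * gradient_magnitude(z)^2)
  expect_true(all(q > 0))
  expect_error(speed_cost_map(z, eps_D = 0), "positive")
  expect_error(speed_cost_map(z, beta_G = -1), "non-negative")
})

test_that("geodesic distance is zero on the source and sup-normalised", {
  z <- toy_image(16, 16)
  src <- matrix(FALSE, 16, 16); src[7:9, 7:9] <- TRUE
  D <- geodesic_distance(z, src)
  expect_true(all(D$values[src] == 0))
  expect_equal(max(D$values), 1)
  expect_true(all(D$values >= 0 & D$values <= 1))
  # whole-domain source -> identically zero
  D0 <- geodesic_distance(z, matrix(TRUE, 16, 16))
  expect_true(all(D0$values == 0))
  expect_error(geodesic_distance(z, matrix(FALSE, 16, 16)), "empty")
})

test_that("constant-cost distance matches Dijkstra within discretisation error", {
  # single source on a constant image, q = c everywhere
  for (cst in c(1, 2.5)) {
    z <- matrix(0.5, 11, 11)
    src <- matrix(FALSE, 11, 11); src[6, 6] <- TRUE
    D <- geodesic_distance(z, src, eps_D = cst, beta_G = 0)
    dj <- oracle_dijkstra(matrix(cst, 11, 11), src)
    # both approximate c * euclidean distance. In the far field the
    # 8-connected chamfer metric overestimates by up to sec(pi/8) - 1
    # ~ 8.2% and the first-order upwind scheme carries its own few percent:
    # allow 15% relative. Adjacent to a point source the upwind stencil's
    # relative error is O(1) (diagonal neighbour: (2+sqrt(2))/2 vs sqrt(2))
    # and decays with distance, so the near field is held to an absolute
    # band of one grid step instead.
    far <- !src & dj > 3 * cst
    expect_lt(max(abs(D$raw[far] - dj[far]) / dj[far]), 0.15)
    expect_lt(max(abs(D$raw - dj)), 1.0 * cst)
    # linear scaling in a constant q: raw doubles, normalised invariant
    D2 <- geodesic_distance(z, src, eps_D = 2 * cst, beta_G = 0)
    expect_equal(D2$raw, 2 * D$raw, tolerance = 1e-10)
    expect_equal(D2$values, D$values, tolerance = 1e-10)
  }
})

test_that("distance accumulates across image edges, not along flat regions", {
  # two flat halves separated by a step edge: the geodesic cost is tiny on
  # the source side and jumps across the edge column
  z <- matrix(0.2, 24, 24); z[, 13:24] <- 0.8
  src <- matrix(FALSE, 24, 24); src[12, 4] <- TRUE
  D <- geodesic_distance(z, src, eps_D = 1e-3, beta_G = 1000)
  same_side <- D$raw[12, 10]   # flat path, far in pixels
  across <- D$raw[12, 16]      # crosses the edge, similar pixel distance
  expect_gt(across, 10 * same_side)
  # the normalised map is governed by the far side
  expect_lt(max(D$values[, 1:11]), 0.2)
  # with beta_G = 0 the same geometry has no barrier
  D0 <- geodesic_distance(z, src, eps_D = 1e-3, beta_G = 0)
  expect_lt(D0$raw[12, 16] / D0$raw[12, 10], 3)
})

test_that("unit-cost geodesic equals the normalised euclidean distance transform", {
  src <- matrix(FALSE, 24, 24); src[10:12, 8:10] <- TRUE
  z <- matrix(0.5, 24, 24)
  D <- geodesic_distance(z, src, eps_D = 1, beta_G = 0)
  edt <- oracle_edt(src)
  expect_lt(max(abs(D$values - edt / max(edt))), 0.05)
})

test_that("enlarging the source never increases the distance", {
  z <- toy_image(16, 16)
  s1 <- matrix(FALSE, 16, 16); s1[8, 8] <- TRUE
  s2 <- s1; s2[3, 12] <- TRUE; s2[13, 4] <- TRUE
  d1 <- geodesic_distance(z, s1)$raw
  d2 <- geodesic_distance(z, s2)$raw
  expect_true(all(d2 <= d1 + 1e-12))
})
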