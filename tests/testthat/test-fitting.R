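test_that("asymmetric background term is a tent peaking at c1", {
  z <- matrix(seq(0, 1, length.out = 121), 11, 11)
  f2 <- pm_background(z, c1 = 0.5, gamma1 = 0.2, gamma2 = 0.1)
  expect_true(all(f2 >= 0 & f2 <= 1))
  expect_equal(pm_background(matrix(0.5, 3, 3), 0.5, 0.2, 0.1)[1, 1], 1)
  expect_equal(pm_background(matrix(0.3, 3, 3), 0.5, 0.2, 0.1)[1, 1], 0)
  expect_equal(pm_background(matrix(0.6, 3, 3), 0.5, 0.2, 0.1)[1, 1], 0)
  expect_equal(pm_background(matrix(0.45, 3, 3), 0.5, 0.2, 0.1)[1, 1], 0.75)
  expect_equal(pm_background(matrix(0.55, 3, 3), 0.5, 0.2, 0.1)[1, 1], 0.5)
  # attains 1 only at z = c1
  expect_true(all(f2[abs(z - 0.5) > 1e-9] < 1))
  # continuity/piecewise linearity on a fine 1-D grid
  u <- seq(0, 1, by = 1e-3)
  fv <- pm_background(matrix(u, 1001, 1), 0.5, 0.2, 0.1)[, 1]
  expect_lt(max(abs(diff(fv))), 1.1 * 1e-3 / 0.1) # slope bounded by 1/gamma2
  expect_error(pm_background(z, 0.5, 0, 0.1), "positive")
})

test_that("proposed fitting combines quadratic foreground and tent background", {
  zin <- matrix(0.5, 4, 4)
  expect_true(all(pm_fitting(zin, 0.5, 0.25, 0.25) == -1))
  zfar <- matrix(0.95, 4, 4)
  expect_equal(pm_fitting(zfar, 0.5, 0.25, 0.25),
               matrix(0.45^2, 4, 4))
  expect_equal(pm_fitting(matrix(0.6, 2, 2), 0.5, 0.25, 0.25)[1, 1],
               0.01 - 0.6)
})

test_that("Chan-Vese fitting and its degenerate equal-constant case", {
  z <- toy_image()
  expect_true(all(cv_fitting(z, 0.4, 0.4) == 0))
  expect_equal(cv_fitting(matrix(0.3, 2, 2), 0.1, 0.8)[1, 1], -0.21)
  expect_equal(cv_fitting(matrix(0.1, 2, 2), 0.1, 0.8)[1, 1], -0.49)
})

test_that("RSF recovers region means on piecewise-constant images", {
  z <- matrix(0.2, 16, 16); z[4:13, 4:13] <- 0.9
  ug <- z > 0.5
  # constant image: f identically 0 (up to fp) under any labeling
  zc <- matrix(0.6, 16, 16)
  expect_lt(max(abs(suppressWarnings(rsf_fitting(zc, ug, sigma = 2)))), 1e-12)
  # piecewise-constant with the exact partition: z is constant within each
  # class, so the localised means equal the region means (0.9, 0.2) exactly
  # and f = E[(z-0.9)^2] - E[(z-0.2)^2] under the kernel smoothing; check
  # against the direct-convolution oracle
  k <- selectseg:::.gauss_kernel(2)
  Ez <- oracle_conv2(z, k); Ez2 <- oracle_conv2(z^2, k)
  want <- (Ez2 - 2 * 0.9 * Ez + 0.81) - (Ez2 - 2 * 0.2 * Ez + 0.04)
  f <- rsf_fitting(z, ug, sigma = 2)
  expect_equal(f, want, tolerance = 1e-10)
  # deep inside each region the sign favours the correct class
  expect_lt(f[8, 8], 0)
  expect_gt(f[1, 1], 0)
})

test_that("separable convolution matches the direct 2-D oracle", {
  set.seed(7)
  x <- matrix(runif(64), 8, 8)
  k <- selectseg:::.gauss_kernel(1)
  expect_equal(selectseg:::.sep_conv2(x, k), oracle_conv2(x, k),
               tolerance = 1e-12)
  kb <- selectseg:::.box_kernel(3)
  expect_equal(selectseg:::.sep_conv2(x, kb), oracle_conv2(x, kb),
               tolerance = 1e-12)
})

test_that("LCV reduces to scaled Chan-Vese when the local weight vanishes", {
  z <- matrix(0.2, 9, 9); z[2:5, 2:5] <- 0.8
  ug <- z > 0.5
  alpha <- 1.7
  f <- lcv_fitting(z, ug, window_k = 3, alpha_w = alpha, beta_w = 0)
  c1 <- mean(z[ug]); c2 <- mean(z[!ug])
  expect_equal(f, alpha * cv_fitting(z, c1, c2), tolerance = 1e-12)
  # constant image: difference image vanishes, f identically 0
  expect_lt(max(abs(suppressWarnings(
    lcv_fitting(matrix(0.4, 9, 9), ug, 3)))), 1e-12)
  # d constants equal the class means of z* - z
  zs <- selectseg:::.sep_conv2(z, selectseg:::.box_kernel(3))
  d1 <- mean((zs - z)[ug])
  fq <- lcv_fitting(z, ug, window_k = 3, alpha_w = 0, beta_w = 1)
  expect_equal(fq, ((zs - z) - d1)^2 - ((zs - z) - mean((zs - z)[!ug]))^2,
               tolerance = 1e-12)
})

test_that("hybrid fitting is LCV on the product image", {
  z <- matrix(0.2, 9, 9); z[2:5, 2:5] <- 0.8
  ug <- z > 0.5
  # k = 1: w = z^2, local terms vanish, so alpha-weighted CV on z^2
  f <- hyb_fitting(z, ug, window_k = 1, alpha_w = 2, beta_w = 1)
  w <- z^2
  expect_equal(f, 2 * cv_fitting(w, mean(w[ug]), mean(w[!ug])),
               tolerance = 1e-12)
  expect_lt(max(abs(suppressWarnings(
    hyb_fitting(matrix(0.4, 9, 9), ug, 3)))), 1e-12)
  # w* at the centre of a ramp equals the box mean of z* z
  zr <- matrix(seq(0.1, 0.9, length.out = 81), 9, 9)
  zs <- selectseg:::.sep_conv2(zr, selectseg:::.box_kernel(3))
  ws <- selectseg:::.sep_conv2(zs * zr, selectseg:::.box_kernel(3))
  expect_equal(ws[5, 5], mean((zs * zr)[4:6, 4:6]), tolerance = 1e-12)
})

test_that("generalised-average constants: power means with beta = 1 as CV", {
  z <- matrix(0.2, 8, 8); z[2:4, 2:4] <- 0.8
  ug <- z > 0.5
  cc <- gav_constants(z, ug, 1, 1)
  expect_equal(unname(cc["c1"]), mean(z[ug]))
  expect_equal(unname(cc["c2"]), mean(z[!ug]))
  # constant image: any exponents give the constant
  zc <- matrix(0.6, 8, 8)
  cc2 <- suppressWarnings(gav_constants(zc, ug, 3, -1))
  expect_equal(unname(cc2), c(0.6, 0.6), tolerance = 1e-9)
  # direct evaluation: foreground {0.2, 0.8}, beta1 = 2 -> 0.68
  z2 <- matrix(0.5, 4, 4); z2[1, 1] <- 0.2; z2[1, 2] <- 0.8
  m <- matrix(FALSE, 4, 4); m[1, 1:2] <- TRUE
  expect_equal(unname(gav_constants(z2, m, 2, 1)["c1"]), 0.68)
  # exponents pull towards region extrema (non-constant regions)
  zx <- z; zx[2, 2] <- 0.6; zx[6, 6] <- 0.05
  ccx <- gav_constants(zx, ug, 1, 1)
  cc3 <- gav_constants(zx, ug, 4, -2)
  expect_gt(cc3[["c1"]], ccx[["c1"]])
  expect_lt(cc3[["c2"]], ccx[["c2"]])
  expect_equal(dim(gav_exponent_pairs()), c(8L, 2L))
})

test_that("assembled data field is sup-normalised", {
  z <- toy_image(16, 16)
  src <- matrix(FALSE, 16, 16); src[7:9, 7:9] <- TRUE
  D <- geodesic_distance(z, src)
  f <- pm_fitting(z, 0.8, 0.2, 0.2)
  ff <- assemble_field(f, D, theta = 3)
  expect_equal(max(abs(ff$F_values)), 1)
  expect_equal(ff$r_values, 3 * D$values + f)
  # theta = 0: pure fitting rescale
  f0 <- assemble_field(f, D, theta = 0)
  expect_equal(f0$F_values, f / max(abs(f)))
  # f = 0: F equals the (already normalised) distance
  fz <- assemble_field(f * 0, D, theta = 2)
  expect_equal(fz$F_values, D$values)
  # identically-zero field stays zero
  expect_true(all(assemble_field(f * 0, D$values * 0, 0)$F_values == 0))
  expect_error(assemble_field(f[1:4, 1:4], D, 1), "mismatch")
})
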