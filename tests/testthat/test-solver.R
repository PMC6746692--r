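test_that("one AOS step matches the dense linear-algebra oracle", {
  set.seed(5)
  for (dims in list(c(9, 9), c(12, 16), c(16, 16))) {
    u <- matrix(runif(prod(dims)), dims[1], dims[2])
    g <- matrix(runif(prod(dims), 0.2, 1), dims[1], dims[2])
    Fv <- matrix(runif(prod(dims), -1, 1), dims[1], dims[2])
    lambda <- 4; ctl <- selseg_control()
    alpha <- lambda
    f0 <- lambda * Fv + alpha * selectseg:::.nu_prime(u, ctl$eps2)
    bt <- b_tilde_mask(u, ctl$zeta, taylor_b_coefficient(ctl$eps2))
    got <- aos_iterate(u, Fv, g, lambda, ctl)
    want <- oracle_aos_step(u, g, f0, bt, ctl$tau, alpha, ctl$eps1)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("pure diffusion preserves constants and the mean", {
  u <- matrix(0.37, 10, 10)
  g <- matrix(1, 10, 10)
  ctl <- selseg_control(alpha = 0)
  # constant field, no forcing: fixed point
  out <- aos_iterate(u, matrix(0, 10, 10), g, lambda = 0, ctl)
  expect_equal(out, u, tolerance = 1e-12)
  # non-constant u, zero forcing: Neumann diffusion conserves the mean
  set.seed(2)
  u2 <- matrix(runif(100), 10, 10)
  out2 <- aos_iterate(u2, matrix(0, 10, 10), g, lambda = 0, ctl)
  expect_equal(mean(out2), mean(u2), tolerance = 1e-12)
  expect_lt(stats::sd(out2), stats::sd(u2)) # smoothing
})

test_that("near-linear regime matches a closed-form implicit heat step", {
  # g = 1 and eps1 >> |grad u| make G ~ 1/eps1: each direction is an
  # implicit heat step (I - (2 tau / eps1) L)^{-1} with Neumann Laplacian L
  n <- 8
  u <- matrix(rep(sin(seq(0, pi, length.out = n)), n), n, n) * 1e-4
  eps1 <- 10
  ctl <- selseg_control(eps1 = eps1, alpha = 0)
  out <- aos_iterate(u, matrix(0, n, n), matrix(1, n, n), lambda = 0, ctl)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1) { L[i, i - 1] <- 1; L[i, i] <- L[i, i] - 1 }
    if (i < n) { L[i, i + 1] <- 1; L[i, i] <- L[i, i] - 1 }
  }
  M <- diag(n) - (2 * ctl$tau / eps1) * L
  x1 <- apply(u, 2, function(col) solve(M, col))
  x2 <- t(apply(u, 1, function(row) solve(M, row)))
  expect_equal(out, (x1 + x2) / 2, tolerance = 1e-6 * max(abs(u)))
})

test_that("thresholding is strict and matches elementwise comparison", {
  expect_true(all(threshold_labeling(matrix(0.6, 3, 3), 0.5)))
  expect_false(any(threshold_labeling(matrix(0.5, 3, 3), 0.5)))
  set.seed(8)
  u <- matrix(runif(25), 5, 5)
  expect_identical(threshold_labeling(u, 0.3), u > 0.3)
  expect_error(threshold_labeling(u, 0), "strictly inside")
  expect_error(threshold_labeling(u, 1), "strictly inside")
})

test_that("energy is non-increasing and the fit converges on a fixture", {
  fx <- make_equal_mean_fixture(shape = c(96, 96), seed = 1)
  P <- default_markers(fx$gt, seed = 1)
  fit <- selseg(fx$image, P, model = "pm", lambda = 5, theta = 5)
  expect_true(fit$converged)
  expect_lte(fit$trace$change[fit$iterations], fit$control$tol)
  # semi-implicit slack: 0.1% of the total energy drop
  dE <- diff(fit$trace$energy)
  slack <- 1e-3 * (max(fit$trace$energy) - min(fit$trace$energy))
  expect_true(all(dE <= slack))
  # relaxed labels stay near the box (penalty, not clipping)
  expect_gt(min(fit$u), -0.1)
  expect_lt(max(fit$u), 1.1)
  expect_gt(tanimoto(fit$mask, fx$gt), 0.95)
})

test_that("the thresholded result is insensitive to the initialisation", {
  fx <- make_equal_mean_fixture(shape = c(96, 96), seed = 1)
  P <- default_markers(fx$gt, seed = 1)
  f1 <- selseg(fx$image, P, model = "pm", lambda = 5, theta = 5,
               keep_trace = FALSE)
  f2 <- selseg(fx$image, P, model = "pm", lambda = 5, theta = 5,
               u_init = matrix(0.5, 96, 96), keep_trace = FALSE)
  expect_lt(mean(f1$mask != f2$mask), 0.005)
})

test_that("a dominant distance weight confines the mask near the markers", {
  fx <- make_equal_mean_fixture(shape = c(96, 96), seed = 1)
  P <- default_markers(fx$gt, seed = 1)
  fit <- selseg(fx$image, P, model = "pm", lambda = 1, theta = 200,
                keep_trace = FALSE)
  expect_true(all(fit$mask <= dilate_mask(P$mask, 3)))
})

test_that("fit object methods expose coefficients, masks and residuals", {
  fx <- make_equal_mean_fixture(shape = c(96, 96), seed = 1)
  P <- default_markers(fx$gt, seed = 1)
  fit <- selseg(fx$image, P, model = "pm", lambda = 5, theta = 5, gt = fx$gt)
  co <- coef(fit)
  expect_equal(unname(co["c1"]), 0.5)
  expect_true(all(c("gamma1", "gamma2", "lambda", "theta") %in% names(co)))
  expect_identical(predict(fit), fit$mask)
  expect_identical(predict(fit, gamma = 0.9), fit$u > 0.9)
  expect_identical(fitted(fit), fit$u)
  expect_equal(dim(residuals(fit)), dim(fx$image))
  expect_equal(fit$tc, tanimoto(fit$mask, fx$gt))
  expect_output(print(fit), "Selective segmentation")
  expect_output(summary(fit), "penalty band")
})

test_that("baseline models run through the same solver contract", {
  fx <- make_contrast_fixture(shape = c(96, 96), seed = 1)
  P <- default_markers(fx$gt, seed = 1)
  ctl <- selseg_control(max_iter = 150)
  for (m in c("cv", "gav", "lcv")) {
    fit <- suppressWarnings(
      selseg(fx$image, P, model = m, lambda = 5, theta = 5, control = ctl,
             keep_trace = FALSE))
    expect_s3_class(fit, "selseg")
    expect_true(is.logical(fit$mask))
  }
  # on the contrast fixture (c1 = 0.75 vs background mean 0.49) CV can
  # segment the target well once the data weight outweighs the distance
  # term (its fitting signal is weak relative to the tent term's)
  fit_cv <- selseg(fx$image, P, model = "cv", lambda = 10, theta = 2,
                   keep_trace = FALSE)
  expect_gt(tanimoto(fit_cv$mask, fx$gt), 0.9)
})
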