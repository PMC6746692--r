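#' Solver control parameters
#'
#' Numerical parameters of the modified AOS minimisation. Defaults follow
#' standard practice for this scheme: time step `tau = 1e-2`, TV
#' regularisation floor `eps1 = 1e-4`, penalty smoothing `eps2 = 0.1`,
#' stopping tolerance `tol = 1e-4` on the mean absolute per-pixel change.
#'
#' @param tau time step of the semi-implicit scheme.
#' @param eps1 floor inside |grad u| avoiding TV singularities.
#' @param eps2 smoothing of the exact penalty.
#' @param alpha penalty weight; `NULL` (default) sets alpha = lambda, which
#'   satisfies the enforcement condition alpha > lambda/2 * max|F| since the
#'   data field is sup-normalised to 1.
#' @param zeta half-width of the penalty activation band around {0, 1}.
#' @param tol stopping tolerance (mean absolute change per pixel).
#' @param max_iter iteration cap.
#' @return list of class `"selseg_control"`.
#' @export
selseg_control <- function(tau = 1e-2, eps1 = 1e-4, eps2 = 0.1, alpha = NULL,
                           zeta = 1e-2, tol = 1e-4, max_iter = 2000L) {
  stopifnot(tau > 0, eps1 > 0, eps2 > 0, zeta > 0, tol > 0, max_iter >= 1)
  structure(list(tau = tau, eps1 = eps1, eps2 = eps2, alpha = alpha,
                 zeta = zeta, tol = tol, max_iter = as.integer(max_iter)),
            class = "selseg_control")
}

#' One modified AOS iteration
#'
#' Performs a single semi-implicit step of
#' du/dt = div(G(u) grad u) - f0, with G(u) = g / |grad u|_eps1 and
#' f0 = lambda * F + alpha * nu'(u). The step splits the 2-D diffusion into
#' two 1-D tridiagonal solves (zero-flux ends, Thomas algorithm) that are
#' averaged; the penalty contributes a diagonal damping tau * alpha * btilde
#' on pixels in the activation band.
#'
#' @param u numeric matrix, current relaxed labeling.
#' @param F numeric matrix, sup-normalised data field (see
#'   [assemble_field()]), or a `"fitting_field"`.
#' @param g numeric matrix, edge weight map.
#' @param lambda global data weight.
#' @param control a [selseg_control()] list.
#' @return numeric matrix, the updated labeling.
#' @export
aos_iterate <- function(u, F, g, lambda, control = selseg_control()) {
  Fv <- if (inherits(F, "fitting_field")) F$F_values else F
  stopifnot(identical(dim(u), dim(Fv)), identical(dim(u), dim(g)))
  alpha <- if (is.null(control$alpha)) lambda else control$alpha
  f0 <- lambda * Fv + alpha * .nu_prime(u, control$eps2)
  bt <- b_tilde_mask(u, control$zeta, taylor_b_coefficient(control$eps2))
  aos_step_cpp(u, g, f0, bt, control$tau, alpha, control$eps1)
}

# discrete energy of the unconstrained functional, same stencils as the solver
.discrete_energy <- function(u, g, Fv, lambda, alpha, eps2) {
  gr <- .grad_components(u)
  sum(g * sqrt(gr$gr^2 + gr$gc^2)) + lambda * sum(Fv * u) +
    alpha * sum(.nu_value(u, eps2))
}

#' Threshold a relaxed labeling
#'
#' Binary foreground mask \{u > gamma\} (strict inequality). By convexity of
#' the relaxed problem any gamma in (0, 1) yields an equally valid minimiser
#' of the binary problem; 0.5 is the conventional choice.
#'
#' @param u numeric matrix of relaxed labels, or a `"selseg"` fit.
#' @param gamma threshold in (0, 1).
#' @return logical matrix.
#' @export
threshold_labeling <- function(u, gamma = 0.5) {
  if (inherits(u, "selseg")) u <- u$u
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma >= 1)
    stop("'gamma' must lie strictly inside (0, 1)")
  u > gamma
}

#' Fit a selective segmentation model
#'
#' Minimises the convex selective-segmentation functional
#' TV_g(u) + lambda <F, u> + alpha <nu(u)> over the relaxed labeling
#' u in \[0,1\], where F is the sup-normalised sum of a signed intensity
#' fitting term and the geodesic distance penalty theta * D anchored at the
#' user marker polygon. The minimiser is thresholded at gamma = 0.5 into a
#' binary foreground mask.
#'
#' Fitting models: `"pm"` (asymmetric tent background term with automatic
#' Otsu-based widths, foreground constant fixed at the marker-region mean),
#' `"cv"` (Chan-Vese), `"rsf"` (region-scalable), `"lcv"` (local Chan-Vese),
#' `"hyb"` (hybrid), `"gav"` (generalised averages). For all models except
#' `"pm"` the intensity constants are refreshed each iteration from the
#' current thresholded labeling.
#'
#' @param z numeric matrix, greyscale image with intensities in \[0,1\]
#'   (use [normalize_image()] first if needed).
#' @param markers k x 2 matrix of ordered (row, col) marker points, or a
#'   `"marker_region"`.
#' @param model fitting model id.
#' @param lambda global data weight (lambda-tilde).
#' @param theta selection (distance) weight.
#' @param gammas optional c(gamma1, gamma2) for `model = "pm"`; `NULL`
#'   selects them automatically via [multi_otsu()] and
#'   [gamma_from_thresholds()].
#' @param beta_edge edge sensitivity of the TV weight g (default 1000).
#' @param eps_D,beta_G parameters of the geodesic speed cost q.
#' @param n_classes,n_bins Otsu settings for the automatic width selection.
#' @param model_args named list of model-specific settings: `sigma` (rsf),
#'   `window_k`, `alpha_w`, `beta_w` (lcv/hyb), `beta1`, `beta2` (gav).
#' @param u_init optional initial labeling matrix; default is the indicator
#'   of the marker polygon (by convexity this affects speed, not the result).
#' @param gt optional ground-truth logical matrix; if supplied the Tanimoto
#'   coefficient of the final mask is stored.
#' @param control a [selseg_control()] list.
#' @param keep_trace store the per-iteration change/energy table (default
#'   TRUE).
#' @return object of class `"selseg"`; see [print.selseg()],
#'   [summary.selseg()], [coef.selseg()], [predict.selseg()],
#'   [plot.selseg()].
#' @examples
#' fx <- make_equal_mean_fixture(shape = c(96, 96), seed = 1)
#' P <- default_markers(fx$gt, seed = 1)
#' fit <- selseg(fx$image, P, model = "pm", lambda = 5, theta = 5)
#' fit
#' tanimoto(predict(fit), fx$gt)
#' @export
selseg <- function(z, markers, model = c("pm", "cv", "rsf", "lcv", "hyb", "gav"),
                   lambda = 5, theta = 5, gammas = NULL, beta_edge = 1000,
                   eps_D = 1e-3, beta_G = 1000, n_classes = 3, n_bins = 256,
                   model_args = list(), u_init = NULL, gt = NULL,
                   control = selseg_control(), keep_trace = TRUE) {
  model <- match.arg(model)
  cl <- match.call()
  stopifnot(is.matrix(z), is.numeric(z))
  if (min(z) < 0 || max(z) > 1)
    stop("image intensities must lie in [0,1]; apply normalize_image() first")
  if (lambda < 0 || theta < 0) stop("'lambda' and 'theta' must be non-negative")
  P <- if (inherits(markers, "marker_region")) markers else
    polygon_region(markers, dim(z))
  if (!identical(dim(P$mask), dim(z)))
    stop("marker region shape does not match the image")

  g <- edge_map(z, beta_edge)
  D <- geodesic_distance(z, P, eps_D = eps_D, beta_G = beta_G)
  c1 <- c1_from_region(z, P)

  ma <- modifyList(list(sigma = 3, window_k = 3, alpha_w = 1, beta_w = 1,
                        beta1 = 1.5, beta2 = 0.5), model_args)

  otsu <- NULL
  if (model == "pm") {
    if (is.null(gammas)) {
      otsu <- multi_otsu(z, n_classes = n_classes, n_bins = n_bins)
      gammas <- gamma_from_thresholds(c1, otsu)
    } else {
      gammas <- c(gamma1 = unname(gammas[1]), gamma2 = unname(gammas[2]))
    }
  }

  # fitting function for the current thresholded labeling (constants of the
  # baseline models refresh each iteration; the pm term is fixed for the run)
  constants <- c(c1 = c1, c2 = NA_real_)
  fit_field <- function(ug) {
    switch(model,
      pm = pm_fitting(z, c1, gammas[1], gammas[2]),
      cv = {
        cc1 <- .region_mean(z, ug, "foreground")
        cc2 <- .region_mean(z, !ug, "background")
        constants <<- c(c1 = cc1, c2 = cc2)
        cv_fitting(z, cc1, cc2)
      },
      rsf = rsf_fitting(z, ug, sigma = ma$sigma),
      lcv = lcv_fitting(z, ug, window_k = ma$window_k,
                        alpha_w = ma$alpha_w, beta_w = ma$beta_w),
      hyb = hyb_fitting(z, ug, window_k = ma$window_k,
                        alpha_w = ma$alpha_w, beta_w = ma$beta_w),
      gav = {
        cc <- gav_constants(z, ug, ma$beta1, ma$beta2)
        constants <<- cc
        cv_fitting(z, cc[1], cc[2])
      })
  }

  u <- if (is.null(u_init)) P$mask + 0 else u_init
  stopifnot(identical(dim(u), dim(z)))
  alpha <- if (is.null(control$alpha)) lambda else control$alpha
  bcoef <- taylor_b_coefficient(control$eps2)
  refresh <- model != "pm"

  f <- fit_field(threshold_labeling(u))
  Fv <- assemble_field(f, D, theta)$F_values
  tr <- if (keep_trace) matrix(NA_real_, control$max_iter, 3L) else NULL
  converged <- FALSE
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    if (refresh && it > 1L) {
      f <- fit_field(threshold_labeling(u))
      Fv <- assemble_field(f, D, theta)$F_values
    }
    f0 <- lambda * Fv + alpha * .nu_prime(u, control$eps2)
    bt <- b_tilde_mask(u, control$zeta, bcoef)
    u_new <- aos_step_cpp(u, g, f0, bt, control$tau, alpha, control$eps1)
    change <- mean(abs(u_new - u))
    if (keep_trace)
      tr[it, ] <- c(change,
                    .discrete_energy(u_new, g, Fv, lambda, alpha,
                                     control$eps2),
                    sum(bt != 0))
    u <- u_new
    if (change <= control$tol) { converged <- TRUE; break }
  }

  trace <- if (keep_trace)
    data.frame(iter = seq_len(it), change = tr[seq_len(it), 1L],
               energy = tr[seq_len(it), 2L],
               penalty_active = as.integer(tr[seq_len(it), 3L])) else NULL

  mask <- threshold_labeling(u)
  tc <- if (!is.null(gt)) tanimoto(mask, gt) else NULL
  structure(list(
    u = u, mask = mask, model = model, lambda = lambda, theta = theta,
    c1 = c1, gammas = if (model == "pm") gammas else NULL, otsu = otsu,
    constants = constants, model_args = ma, control = control,
    alpha = alpha, markers = P, distance = D, edge = g, image = z,
    trace = trace, iterations = it, converged = converged, tc = tc,
    call = cl), class = "selseg")
}
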