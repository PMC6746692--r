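# --- small separable-convolution helpers (replicate padding) -----------------

.conv1_rows <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(x)
  out <- matrix(0, nr, ncol(x))
  for (s in seq_along(k)) {
    off <- s - r - 1L
    idx <- pmin(pmax(seq_len(nr) + off, 1L), nr)
    out <- out + k[s] * x[idx, , drop = FALSE]
  }
  out
}

.conv1_cols <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  nc <- ncol(x)
  out <- matrix(0, nrow(x), nc)
  for (s in seq_along(k)) {
    off <- s - r - 1L
    idx <- pmin(pmax(seq_len(nc) + off, 1L), nc)
    out <- out + k[s] * x[, idx, drop = FALSE]
  }
  out
}

# separable 2-D convolution with a unit-sum 1-D kernel and replicate padding;
# the implied 2-D kernel is the outer product, so it also sums to 1
.sep_conv2 <- function(x, k) .conv1_cols(.conv1_rows(x, k), k)

.gauss_kernel <- function(sigma, trunc = 4) {
  r <- max(1L, ceiling(trunc * sigma))
  k <- exp(-(((-r):r)^2) / (2 * sigma^2))
  k / sum(k)
}

.box_kernel <- function(k) rep(1 / k, k)

.threshold01 <- function(u) {
  if (is.logical(u)) return(u)
  u > 0.5
}

# region means with empty-region fallback to the global mean
.region_mean <- function(z, sel, what) {
  if (any(sel)) return(mean(z[sel]))
  warning(sprintf("empty %s region; falling back to global mean", what))
  mean(z)
}

# --- proposed asymmetric background term -------------------------------------

#' Asymmetric background fitting function
#'
#' The piecewise-linear tent penalty on intensities near the foreground
#' constant c1: it equals 1 at z = c1, decays linearly to 0 at c1 - gamma1
#' (below) and c1 + gamma2 (above), and is 0 outside that band. Used as the
#' background term of the proposed fitting function, it penalises background
#' pixels of foreground-like intensity regardless of whether the remaining
#' background is brighter or darker than the target, removing the dependence
#' on a single background constant c2.
#'
#' @param z numeric matrix, image in \[0,1\].
#' @param c1 foreground intensity in \[0,1\].
#' @param gamma1,gamma2 strictly positive lower/upper half-widths.
#' @return numeric matrix with values in \[0,1\].
#' @export
pm_background <- function(z, c1, gamma1, gamma2) {
  if (gamma1 <= 0 || gamma2 <= 0)
    stop("'gamma1' and 'gamma2' must be strictly positive")
  dz <- z - c1
  out <- matrix(0, nrow(z), ncol(z))
  lowr <- dz >= -gamma1 & dz <= 0
  uppr <- dz > 0 & dz <= gamma2
  out[lowr] <- 1 + dz[lowr] / gamma1
  out[uppr] <- 1 - dz[uppr] / gamma2
  out
}

#' Proposed fitting function
#'
#' f(x) = lambda1 (z - c1)^2 - lambda2 * tent(z; c1, gamma1, gamma2).
#' Negative values favour foreground labelling, positive values background.
#' The foreground term is the Chan-Vese quadratic around c1; the background
#' term is [pm_background()].
#'
#' @inheritParams pm_background
#' @param lambda1,lambda2 non-negative term weights (default 1; the global
#'   data weight is carried by the solver's `lambda`).
#' @return numeric matrix of signed fitting values.
#' @export
pm_fitting <- function(z, c1, gamma1, gamma2, lambda1 = 1, lambda2 = 1) {
  lambda1 * (z - c1)^2 - lambda2 * pm_background(z, c1, gamma1, gamma2)
}

# --- baseline fitting terms --------------------------------------------------

#' Chan-Vese fitting function
#'
#' f(x) = lambda1 (z - c1)^2 - lambda2 (z - c2)^2, the classical two-phase
#' piecewise-constant fitting term. When the optimal c1 and c2 coincide
#' (backgrounds containing large regions at the target intensity) this term
#' vanishes almost everywhere, which is the failure mode the proposed term
#' addresses.
#'
#' @param z numeric matrix, image in \[0,1\].
#' @param c1,c2 foreground/background intensity constants.
#' @param lambda1,lambda2 non-negative weights.
#' @return numeric matrix of signed fitting values.
#' @export
cv_fitting <- function(z, c1, c2, lambda1 = 1, lambda2 = 1) {
  lambda1 * (z - c1)^2 - lambda2 * (z - c2)^2
}

#' Region-scalable fitting function
#'
#' Kernel-localised means h1, h2 are computed from the previous (thresholded)
#' labeling by Gaussian-weighted ratios, and the fitting function is the
#' difference of the kernel-smoothed squared residuals. Allows intensity
#' inhomogeneity at scale `sigma`.
#'
#' @param z numeric matrix, image in \[0,1\].
#' @param u_prev previous labeling (numeric in \[0,1\] or logical); it is
#'   thresholded at 0.5 before the constant update.
#' @param sigma Gaussian kernel scale in pixels (default 3); the kernel is
#'   truncated at radius 4*sigma and normalised to unit sum.
#' @param lambda1,lambda2 non-negative weights.
#' @return numeric matrix of signed fitting values.
#' @export
rsf_fitting <- function(z, u_prev, sigma = 3, lambda1 = 1, lambda2 = 1) {
  if (sigma <= 0) stop("'sigma' must be positive")
  ug <- .threshold01(u_prev)
  k <- .gauss_kernel(sigma)
  ugn <- ug + 0
  den1 <- .sep_conv2(ugn, k)
  den2 <- .sep_conv2(1 - ugn, k)
  num1 <- .sep_conv2(ugn * z, k)
  num2 <- .sep_conv2((1 - ugn) * z, k)
  h1 <- num1 / den1
  h2 <- num2 / den2
  bad1 <- !is.finite(h1) | den1 <= 0
  bad2 <- !is.finite(h2) | den2 <= 0
  if (any(bad1)) {
    warning("empty local foreground in RSF update; using global foreground mean")
    h1[bad1] <- .region_mean(z, ug, "foreground")
  }
  if (any(bad2)) {
    warning("empty local background in RSF update; using global background mean")
    h2[bad2] <- .region_mean(z, !ug, "background")
  }
  # K * |z(y) - h(x)|^2 expanded with the kernel acting on z only
  # (h is evaluated at the centre pixel); K*1 = 1 by unit-sum + replication
  kz  <- .sep_conv2(z, k)
  kz2 <- .sep_conv2(z^2, k)
  f1 <- kz2 - 2 * h1 * kz + h1^2
  f2 <- kz2 - 2 * h2 * kz + h2^2
  lambda1 * f1 - lambda2 * f2
}

#' Local Chan-Vese fitting function
#'
#' Augments Chan-Vese with a local term on the difference image z* - z,
#' where z* is the k x k box average of z. The constants (c1, c2, d1, d2)
#' are the region means of z and of z* - z over the previous thresholded
#' labeling and its complement.
#'
#' @inheritParams rsf_fitting
#' @param window_k odd box window size (default 3).
#' @param alpha_w,beta_w non-negative weights of the global and local terms
#'   (default 1 each); `beta_w = 0` reduces to alpha-scaled Chan-Vese.
#' @return numeric matrix of signed fitting values.
#' @export
lcv_fitting <- function(z, u_prev, window_k = 3, alpha_w = 1, beta_w = 1) {
  .lcv_like(z, u_prev, window_k, alpha_w, beta_w)
}

#' Hybrid fitting function
#'
#' The local Chan-Vese structure applied to the product image w = z* z
#' (with w* its box average) instead of z, combining the inhomogeneity
#' handling of the blurred image with the contrast of the original.
#'
#' @inheritParams lcv_fitting
#' @return numeric matrix of signed fitting values.
#' @export
hyb_fitting <- function(z, u_prev, window_k = 3, alpha_w = 1, beta_w = 1) {
  if (window_k < 1 || window_k %% 2 == 0) stop("'window_k' must be odd >= 1")
  zs <- .sep_conv2(z, .box_kernel(window_k))
  w <- zs * z
  .lcv_like(w, u_prev, window_k, alpha_w, beta_w)
}

.lcv_like <- function(z, u_prev, window_k, alpha_w, beta_w) {
  if (window_k < 1 || window_k %% 2 == 0) stop("'window_k' must be odd >= 1")
  if (alpha_w < 0 || beta_w < 0) stop("weights must be non-negative")
  ug <- .threshold01(u_prev)
  zs <- .sep_conv2(z, .box_kernel(window_k))
  dzs <- zs - z
  c1 <- .region_mean(z, ug, "foreground")
  c2 <- .region_mean(z, !ug, "background")
  d1 <- .region_mean(dzs, ug, "foreground")
  d2 <- .region_mean(dzs, !ug, "background")
  f1 <- alpha_w * (z - c1)^2 + beta_w * (dzs - d1)^2
  f2 <- alpha_w * (z - c2)^2 + beta_w * (dzs - d2)^2
  f1 - f2
}

#' Generalised-average intensity constants
#'
#' Power-mean updates c1 = sum(z^b1 u) / sum(z^(b1-1) u) over the foreground
#' of the previous labeling (and analogously c2 over the background with
#' exponent b2). Exponents 1 recover the plain region means; large positive
#' (negative) exponents pull the constant towards the region maximum
#' (minimum). Intensities are floored at `eps_z` before powering when an
#' exponent is negative or fractional.
#'
#' @inheritParams rsf_fitting
#' @param beta1,beta2 real exponents for the foreground/background constants.
#' @param eps_z intensity floor guarding z = 0 under negative exponents.
#' @return named numeric vector c(c1, c2).
#' @export
gav_constants <- function(z, u_prev, beta1, beta2, eps_z = 1e-6) {
  ug <- .threshold01(u_prev)
  zc <- z
  if ((beta1 < 1 || beta2 < 1 || beta1 %% 1 != 0 || beta2 %% 1 != 0) &&
      any(z < eps_z)) {
    warning("intensities below eps_z floored before fractional/negative powers")
    zc <- pmax(z, eps_z)
  }
  one_c <- function(sel, b, what) {
    num <- sum(zc[sel]^b)
    den <- sum(zc[sel]^(b - 1))
    if (!any(sel) || !is.finite(num) || !is.finite(den) || den == 0) {
      warning(sprintf("degenerate generalised-average update for %s; using region mean", what))
      return(.region_mean(z, sel, what))
    }
    num / den
  }
  c(c1 = one_c(ug, beta1, "foreground"), c2 = one_c(!ug, beta2, "background"))
}

#' The eight generalised-average exponent pairs searched in benchmarks
#' @return 8 x 2 matrix with columns beta1, beta2.
#' @export
gav_exponent_pairs <- function() {
  m <- rbind(c(1.5, 0.5), c(2, 0), c(3, -1), c(4, -2),
             c(0.5, 1.5), c(0, 2), c(-1, 3), c(-2, 4))
  colnames(m) <- c("beta1", "beta2")
  m
}

# --- assembly ----------------------------------------------------------------

#' Assemble the rescaled data field
#'
#' Combines a fitting function with the geodesic distance penalty:
#' r(x) = theta * D(x) + f(x), then sup-normalises F = r / max|r| so that
#' the data weight is comparable across fitting models. If r is identically
#' zero, F is zero.
#'
#' @param f numeric matrix of signed fitting values.
#' @param D `"distance_map"` or numeric matrix (normalised distances).
#' @param theta non-negative selection weight.
#' @return list of class `"fitting_field"` with `f_values`, `r_values`,
#'   `F_values`.
#' @export
assemble_field <- function(f, D, theta) {
  Dv <- if (inherits(D, "distance_map")) D$values else D
  if (!identical(dim(f), dim(Dv))) stop("shape mismatch between f and D")
  if (theta < 0) stop("'theta' must be non-negative")
  r <- theta * Dv + f
  mx <- max(abs(r))
  Fv <- if (mx > 0) r / mx else r
  structure(list(f_values = f, r_values = r, F_values = Fv),
            class = "fitting_field")
}
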