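# Synthetic benchmark images: a homogeneous target disc, a decoy object of
# the SAME intensity elsewhere in the image (so only the marker constraint
# can discriminate), and two background panels whose areas/values are
# balanced so the mean intensity outside the target hits a requested value.
# The equal-mean variant sets that background mean equal to the target
# intensity (0.50), the designed failure condition of background-constant
# fitting terms; the contrast variant uses 0.75 against 0.49.

.disc_mask <- function(shape, centre, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - centre[1])^2 + (cc - centre[2])^2 <= radius^2
}

.build_fixture <- function(shape, seed, fg_value, bg_mean, decoy_value,
                           noise_sigma) {
  if (any(shape < 96L))
    stop("fixture shape must be at least 96 x 96")
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  sc <- min(shape)
  # deterministic geometry with seed-controlled jitter so different seeds
  # give genuinely different instances even at zero noise
  jit <- function(s) runif(1, -s, s)
  r1 <- 0.16 * sc * runif(1, 0.9, 1.1)
  target <- .disc_mask(shape, c(nr * 0.50 + jit(0.03 * sc),
                                nc * 0.30 + jit(0.03 * sc)), r1)
  r2 <- 0.14 * sc * runif(1, 0.9, 1.1)
  decoy <- .disc_mask(shape, c(nr * 0.28 + jit(0.02 * sc),
                               nc * 0.72 + jit(0.02 * sc)), r2)
  if (any(target & decoy)) stop("fixture geometry infeasible: overlap")
  split_row <- floor(nr * 0.55)
  top <- matrix(FALSE, nr, nc); top[seq_len(split_row), ] <- TRUE
  v1 <- 0.3
  z <- matrix(v1, nr, nc)
  bg <- !target
  panel2 <- bg & !top & !decoy
  a2 <- sum(panel2)
  s_known <- v1 * sum(bg & top & !decoy) + decoy_value * sum(decoy)
  v2 <- (bg_mean * sum(bg) - s_known) / a2
  if (v2 < 0 || v2 > 1)
    stop("fixture area arithmetic infeasible: panel value out of [0,1]")
  z[panel2] <- v2
  z[decoy] <- decoy_value
  z[target] <- fg_value
  if (noise_sigma > 0) {
    z <- z + matrix(rnorm(nr * nc, 0, noise_sigma), nr, nc)
    z <- pmin(pmax(z, 0), 1)
  }
  achieved <- c(fg_mean = mean(z[target]), bg_mean = mean(z[bg]))
  stopifnot(abs(achieved["bg_mean"] - bg_mean) < 1e-2)
  structure(list(image = z, gt = target, decoy = decoy,
                 spec = list(shape = shape, seed = seed, fg_value = fg_value,
                             bg_mean = bg_mean, noise_sigma = noise_sigma,
                             panel_values = c(v1, v2)),
                 achieved = achieved),
            class = "seg_fixture")
}

#' Equal-mean synthetic fixture
#'
#' Piecewise-constant test image whose target disc has intensity 0.50 while
#' the mean of everything outside the target is also 0.50 (within 1e-2): a
#' decoy disc at the same intensity plus two complementary background
#' panels. Optimal Chan-Vese constants on this image satisfy c1 = c2, so
#' fitting terms built on a background constant vanish; the asymmetric
#' background term does not.
#'
#' @param shape c(nrow, ncol), each >= 96 (default 128 x 128).
#' @param seed integer; controls the geometry jitter and any noise.
#' @param noise_sigma Gaussian noise sd (default 0: exactly
#'   piecewise-constant).
#' @return list of class `"seg_fixture"` with `image`, `gt` (target mask),
#'   `decoy`, `spec`, `achieved` (realised region means).
#' @export
make_equal_mean_fixture <- function(shape = c(128L, 128L), seed = 1,
                                    noise_sigma = 0) {
  .build_fixture(shape, seed, fg_value = 0.50, bg_mean = 0.50,
                 decoy_value = 0.50, noise_sigma = noise_sigma)
}

#' Contrast synthetic fixture
#'
#' As [make_equal_mean_fixture()] but with target intensity 0.75 against a
#' background composed to mean 0.49, the regime where background-constant
#' fitting terms also work; the decoy disc still shares the target
#' intensity so selection is required.
#'
#' @inheritParams make_equal_mean_fixture
#' @export
make_contrast_fixture <- function(shape = c(128L, 128L), seed = 1,
                                  noise_sigma = 0) {
  .build_fixture(shape, seed, fg_value = 0.75, bg_mean = 0.49,
                 decoy_value = 0.75, noise_sigma = noise_sigma)
}

#' @export
print.seg_fixture <- function(x, ...) {
  cat(sprintf(
    "Synthetic fixture %d x %d (seed %d): target %d px at %.2f, background mean %.3f\n",
    nrow(x$image), ncol(x$image), x$spec$seed, sum(x$gt), x$spec$fg_value,
    x$achieved["bg_mean"]))
  invisible(x)
}

# Euclidean distance to the background, i.e. depth inside the mask
.interior_depth <- function(mask) {
  q <- matrix(1, nrow(mask), ncol(mask))
  fast_sweep_eikonal(q, !mask, 1e-9, 100L)
}

#' Default marker triangle inside a target mask
#'
#' A deterministic stand-in for user input: three points on a circle of half
#' the target's inradius around its deepest interior point, at angles offset
#' by a seed-derived rotation. Guaranteed to lie strictly inside the target.
#'
#' @param gt logical target mask.
#' @param seed integer controlling the rotation.
#' @return a `"marker_region"`.
#' @export
default_markers <- function(gt, seed = 1) {
  stopifnot(is.matrix(gt))
  d <- .interior_depth(gt)
  r_in <- max(d)
  if (r_in < 3) stop("target too thin to place an inscribed marker triangle")
  ctr <- which(d == r_in, arr.ind = TRUE)[1, ]
  base <- 2 * pi * ((seed * 0.6180339887) %% 1)
  ang <- base + c(0, 2, 4) * pi / 3
  rad <- 0.5 * r_in
  pts <- cbind(round(ctr[1] + rad * sin(ang)), round(ctr[2] + rad * cos(ang)))
  if (!all(gt[pts])) stop("target too thin: default markers fall outside")
  polygon_region(pts, dim(gt))
}

# one random marker triangle with all vertices strictly inside gt; NULL on
# failure after `retries` attempts
.random_marker_triangle <- function(gt, interior_idx, shape, k = 3L,
                                    retries = 50L) {
  for (r in seq_len(retries)) {
    pick <- sample(length(interior_idx), k)
    ij <- arrayInd(interior_idx[pick], shape)
    # reject (near-)collinear triples: shoelace area under 1 pixel
    x <- ij[, 2]; y <- ij[, 1]
    area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    if (area < 1) next
    P <- tryCatch(polygon_region(ij, shape), error = function(e) NULL)
    if (!is.null(P)) return(P)
  }
  NULL
}
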