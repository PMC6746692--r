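#' @export
print.selseg <- function(x, ...) {
  cat(sprintf("Selective segmentation fit (model = %s)\n", x$model))
  cat(sprintf("  grid %d x %d, %d marker points, lambda = %g, theta = %g\n",
              nrow(x$u), ncol(x$u), nrow(x$markers$markers), x$lambda,
              x$theta))
  cat(sprintf("  %s after %d iterations (final change %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations,
              if (!is.null(x$trace)) x$trace$change[x$iterations] else NA))
  cat(sprintf("  foreground: %d pixels (%.1f%%)\n", sum(x$mask),
              100 * mean(x$mask)))
  if (!is.null(x$tc)) cat(sprintf("  Tanimoto vs ground truth: %.4f\n", x$tc))
  invisible(x)
}

#' Summary of a selective segmentation fit
#'
#' @param object a `"selseg"` fit.
#' @param ... unused.
#' @export
summary.selseg <- function(object, ...) {
  x <- object
  print(x)
  cat(sprintf("  c1 (marker-region mean) = %.4f\n", x$c1))
  if (!is.null(x$gammas))
    cat(sprintf("  background penalty band: [%.4f, %.4f] (gamma1 = %.4f, gamma2 = %.4f)\n",
                x$c1 - x$gammas[1], x$c1 + x$gammas[2], x$gammas[1],
                x$gammas[2]))
  if (!is.null(x$otsu))
    cat(sprintf("  Otsu thresholds (N = %d): %s\n", x$otsu$n_classes,
                paste(format(x$otsu$thresholds, digits = 4), collapse = ", ")))
  if (!is.na(x$constants["c2"]))
    cat(sprintf("  final constants: c1 = %.4f, c2 = %.4f\n",
                x$constants["c1"], x$constants["c2"]))
  cat(sprintf("  penalty weight alpha = %g, relaxed u range [%.3f, %.3f]\n",
              x$alpha, min(x$u), max(x$u)))
  if (!is.null(x$trace))
    cat(sprintf("  energy: %.4f -> %.4f over %d iterations\n",
                x$trace$energy[1], x$trace$energy[x$iterations],
                x$iterations))
  invisible(x)
}

#' Coefficients of a selective segmentation fit
#'
#' Returns the intensity constants the fitted model ended with: always `c1`;
#' `gamma1`/`gamma2` for the proposed model; `c2` for models that carry a
#' background constant; plus the tuning weights `lambda` and `theta`.
#'
#' @param object a `"selseg"` fit.
#' @param ... unused.
#' @export
coef.selseg <- function(object, ...) {
  out <- c(c1 = unname(object$constants["c1"]))
  if (!is.na(object$constants["c2"]))
    out <- c(out, c2 = unname(object$constants["c2"]))
  if (!is.null(object$gammas))
    out <- c(out, gamma1 = unname(object$gammas[1]),
             gamma2 = unname(object$gammas[2]))
  c(out, lambda = object$lambda, theta = object$theta)
}

#' @export
fitted.selseg <- function(object, ...) object$u

#' Thresholded segmentation mask
#'
#' @param object a `"selseg"` fit.
#' @param gamma threshold in (0,1); default 0.5.
#' @param ... unused.
#' @return logical foreground mask.
#' @export
predict.selseg <- function(object, gamma = 0.5, ...) {
  threshold_labeling(object$u, gamma)
}

#' Piecewise-constant reconstruction residuals
#'
#' Residuals of the two-constant image model implied by the fit:
#' z - (c1 * mask + c2 * (1 - mask)), with c2 taken as the mean intensity
#' over the fitted background.
#'
#' @param object a `"selseg"` fit.
#' @param ... unused.
#' @export
residuals.selseg <- function(object, ...) {
  c2 <- if (!is.na(object$constants["c2"])) object$constants["c2"] else
    .region_mean(object$image, !object$mask, "background")
  object$image - (object$constants["c1"] * object$mask + c2 * !object$mask)
}

#' Plot a selective segmentation fit
#'
#' Displays the image with the segmentation boundary and the marker points
#' overlaid, or diagnostic panels.
#'
#' @param x a `"selseg"` fit.
#' @param what `"mask"` (image + contour + markers), `"u"` (relaxed label
#'   field), `"distance"` (geodesic penalty), or `"trace"` (energy decay).
#' @param ... passed to [graphics::image()].
#' @export
plot.selseg <- function(x, what = c("mask", "u", "distance", "trace"), ...) {
  what <- match.arg(what)
  show <- function(m, main) {
    image(t(m[nrow(m):1, ]), col = gray(seq(0, 1, length.out = 256)),
          axes = FALSE, main = main, asp = nrow(m) / ncol(m), ...)
  }
  if (what == "trace") {
    if (is.null(x$trace)) stop("fit was run with keep_trace = FALSE")
    plot(x$trace$iter, x$trace$energy, type = "l", xlab = "iteration",
         ylab = "discrete energy")
    return(invisible(x))
  }
  m <- switch(what, mask = x$image, u = x$u, distance = x$distance$values)
  show(m, main = sprintf("selseg (%s)", x$model))
  if (what == "mask") {
    b <- .mask_boundary(x$mask)
    nr <- nrow(x$mask); nc <- ncol(x$mask)
    points((b[, 2] - 1) / (nc - 1), 1 - (b[, 1] - 1) / (nr - 1),
           pch = ".", col = "red", cex = 2)
    mk <- x$markers$markers
    points((mk[, 2] - 1) / (nc - 1), 1 - (mk[, 1] - 1) / (nr - 1),
           pch = 3, col = "green")
  }
  invisible(x)
}

# pixels of a mask with at least one 4-neighbour outside the mask
.mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(mask & !inner, arr.ind = TRUE)
}
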