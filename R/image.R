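#' Normalise a raw image to \[0, 1\]
#'
#' Affinely rescales a 2-D intensity matrix so that its minimum maps to 0 and
#' its maximum to 1. All downstream routines assume intensities in \[0, 1\]
#' (the fitting-term widths, the Otsu thresholds and the edge parameters are
#' all calibrated on that scale).
#'
#' @param raw numeric matrix of finite intensities (any range, e.g. 0..255).
#' @return numeric matrix with values in \[0, 1\].
#' @examples
#' z <- normalize_image(matrix(c(2, 4, 6, 10, 8, 0), 3, 2, byrow = TRUE))
#' range(z)
#' @export
normalize_image <- function(raw) {
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("'raw' must be a numeric matrix")
  if (!all(is.finite(raw)))
    stop("'raw' must contain only finite values")
  lo <- min(raw); hi <- max(raw)
  if (hi == lo)
    stop("degenerate image: constant intensity (max equals min)")
  (raw - lo) / (hi - lo)
}

# Row/column first differences: central in the interior, one-sided at the
# borders. Returned as a list(gr, gc) of matrices the same shape as z.
.grad_components <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  gr <- matrix(0, nr, nc)
  gc <- matrix(0, nr, nc)
  if (nr >= 3L)
    gr[2:(nr - 1L), ] <- (z[3:nr, ] - z[1:(nr - 2L), ]) / 2
  gr[1L, ]  <- z[2L, ] - z[1L, ]
  gr[nr, ]  <- z[nr, ] - z[nr - 1L, ]
  if (nc >= 3L)
    gc[, 2:(nc - 1L)] <- (z[, 3:nc] - z[, 1:(nc - 2L)]) / 2
  gc[, 1L]  <- z[, 2L] - z[, 1L]
  gc[, nc]  <- z[, nc] - z[, nc - 1L]
  list(gr = gr, gc = gc)
}

#' Gradient magnitude of an image
#'
#' Per-pixel Euclidean norm of the two first-difference components, using
#' central differences in the interior and one-sided differences on the
#' border rows/columns (grid spacing 1).
#'
#' @param z numeric matrix (image).
#' @return numeric matrix of |grad z| values, same shape as `z`.
#' @export
gradient_magnitude <- function(z) {
  stopifnot(is.matrix(z), is.numeric(z))
  g <- .grad_components(z)
  sqrt(g$gr^2 + g$gc^2)
}

#' Edge-detector weight map
#'
#' Computes g(|grad z|) = 1 / (1 + beta_edge * |grad z|^2) per pixel. Values
#' lie in (0, 1], equal 1 on flat regions and decrease towards 0 at strong
#' edges; this map weights the total-variation term so contours are cheap
#' along image edges.
#'
#' @param z numeric matrix (image in \[0,1\]).
#' @param beta_edge non-negative edge-sensitivity parameter; 0 gives plain
#'   (unweighted) TV. Default 1000 on the normalised intensity scale.
#' @return numeric matrix of weights in (0, 1\].
#' @export
edge_map <- function(z, beta_edge = 1000) {
  if (!is.numeric(beta_edge) || length(beta_edge) != 1L || beta_edge < 0)
    stop("'beta_edge' must be a single non-negative number")
  s <- gradient_magnitude(z)
  1 / (1 + beta_edge * s^2)
}
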