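#' Marker polygon region
#'
#' Rasterises the ordered user marker points into the filled polygon region
#' used as the seed of the selective segmentation: its interior is assumed to
#' lie inside the target object, it anchors the geodesic distance penalty
#' (distance 0 on the region) and its mean intensity fixes the foreground
#' constant c1.
#'
#' Coordinates are (row, col), 1-based, pixel-centred; a pixel belongs to the
#' region when its centre is inside or on the polygon boundary.
#'
#' @param markers k x 2 numeric matrix (or data frame) of ordered (row, col)
#'   marker coordinates, k >= 3, forming a simple (non-self-intersecting),
#'   non-degenerate polygon inside the grid.
#' @param shape integer vector c(nrow, ncol) of the image grid.
#' @return An object of class `"marker_region"`: a list with elements
#'   `markers` (the input points, in order) and `mask` (logical matrix of the
#'   filled polygon).
#' @examples
#' p <- polygon_region(rbind(c(2, 2), c(2, 8), c(8, 2)), c(12, 12))
#' sum(p$mask)
#' @export
polygon_region <- function(markers, shape) {
  markers <- as.matrix(markers)
  if (!is.numeric(markers) || ncol(markers) != 2L)
    stop("'markers' must be a k x 2 numeric matrix of (row, col) points")
  k <- nrow(markers)
  if (k < 3L)
    stop("at least 3 marker points are required")
  if (length(shape) != 2L || any(shape < 3L))
    stop("'shape' must be c(nrow, ncol), both >= 3")
  if (any(markers[, 1L] < 1 | markers[, 1L] > shape[1L] |
          markers[, 2L] < 1 | markers[, 2L] > shape[2L]))
    stop("marker points out of grid bounds")
  # shoelace area; zero means collinear/degenerate
  r <- markers[, 1L]; cc <- markers[, 2L]
  rs <- c(r[-1L], r[1L]); cs <- c(cc[-1L], cc[1L])
  area2 <- abs(sum(cc * rs - cs * r))
  if (area2 < .Machine$double.eps^0.5)
    stop("marker points are collinear (degenerate polygon)")
  if (.self_intersects(markers))
    stop("marker polygon is self-intersecting")
  grid_r <- rep(seq_len(shape[1L]), times = shape[2L])
  grid_c <- rep(seq_len(shape[2L]), each = shape[1L])
  inside <- pracma::inpolygon(grid_c, grid_r, cc, r, boundary = TRUE)
  mask <- matrix(inside, shape[1L], shape[2L])
  if (!any(mask))
    stop("marker polygon rasterises to an empty region")
  structure(list(markers = markers, mask = mask), class = "marker_region")
}

# Proper-crossing test between all pairs of non-adjacent polygon edges.
.self_intersects <- function(pts) {
  k <- nrow(pts)
  nxt <- c(seq_len(k)[-1L], 1L)
  orient <- function(a, b, c)
    sign((b[2] - a[2]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[2] - a[2]))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      # skip adjacent edges (they share an endpoint)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      a <- pts[i, ]; b <- pts[nxt[i], ]; c <- pts[j, ]; d <- pts[nxt[j], ]
      o1 <- orient(a, b, c); o2 <- orient(a, b, d)
      o3 <- orient(c, d, a); o4 <- orient(c, d, b)
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        return(TRUE)
    }
  }
  FALSE
}

#' @export
print.marker_region <- function(x, ...) {
  cat(sprintf("Marker region: %d points, %d pixels on a %d x %d grid\n",
              nrow(x$markers), sum(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Mean intensity inside the marker region
#'
#' The foreground intensity estimate c1: the arithmetic mean of the image
#' over the pixels of the marker polygon. For approximately homogeneous
#' targets this is kept fixed throughout the minimisation.
#'
#' @param z numeric matrix, image in \[0,1\].
#' @param P a `"marker_region"` (or a logical matrix mask).
#' @return scalar mean intensity.
#' @export
c1_from_region <- function(z, P) {
  mask <- if (inherits(P, "marker_region")) P$mask else P
  stopifnot(is.matrix(z), identical(dim(z), dim(mask)))
  if (!any(mask)) stop("empty marker region")
  mean(z[mask])
}
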