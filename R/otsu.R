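#' Multi-level Otsu thresholds
#'
#' Partitions the intensity histogram into `n_classes` classes by exhaustive
#' search over bin boundaries, maximising the between-class variance
#' (equivalently minimising the intra-class variance). Thresholds are
#' reported at bin upper edges on \[0,1\]; ties in the objective are broken
#' towards the lexicographically smallest threshold vector.
#'
#' @param z numeric matrix, image in \[0,1\].
#' @param n_classes number of classes N >= 2 (default 3; exhaustive search
#'   supported for N <= 4).
#' @param n_bins histogram resolution (default 256).
#' @return list of class `"otsu_thresholds"` with `thresholds` (N-1 strictly
#'   increasing values in (0,1)), `n_classes`, `n_bins`.
#' @export
multi_otsu <- function(z, n_classes = 3, n_bins = 256) {
  stopifnot(is.matrix(z) || is.numeric(z))
  if (n_classes < 2 || n_classes > 4)
    stop("'n_classes' must be between 2 and 4")
  v <- as.numeric(z)
  if (any(v < 0 | v > 1)) stop("intensities must lie in [0,1]")
  bin <- pmin(floor(v * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  if (sum(counts > 0L) < n_classes)
    stop("fewer distinct intensity bins than classes; lower 'n_classes'")
  p <- counts / sum(counts)
  centres <- (seq_len(n_bins) - 0.5) / n_bins
  W <- cumsum(p)              # cumulative weight up to bin b
  M <- cumsum(p * centres)    # cumulative intensity mass
  # between-class contribution of class (a, b] (bins a+1..b), a,b in 0..n_bins
  cls <- function(a, b) {
    w <- W[b] - if (a > 0L) W[a] else 0
    if (w <= 0) return(-Inf)  # empty class is inadmissible
    m <- M[b] - if (a > 0L) M[a] else 0
    m * m / w
  }
  nK <- as.integer(n_classes)
  best <- -Inf
  best_b <- NULL
  bounds <- seq_len(n_bins - 1L)
  if (nK == 2L) {
    for (t1 in bounds) {
      obj <- cls(0L, t1) + cls(t1, n_bins)
      if (obj > best) { best <- obj; best_b <- t1 }
    }
  } else if (nK == 3L) {
    for (t1 in seq_len(n_bins - 2L)) {
      c0 <- cls(0L, t1)
      if (!is.finite(c0)) next
      for (t2 in (t1 + 1L):(n_bins - 1L)) {
        obj <- c0 + cls(t1, t2) + cls(t2, n_bins)
        if (obj > best) { best <- obj; best_b <- c(t1, t2) }
      }
    }
  } else {
    for (t1 in seq_len(n_bins - 3L)) {
      c0 <- cls(0L, t1)
      if (!is.finite(c0)) next
      for (t2 in (t1 + 1L):(n_bins - 2L)) {
        c1v <- cls(t1, t2)
        if (!is.finite(c1v)) next
        for (t3 in (t2 + 1L):(n_bins - 1L)) {
          obj <- c0 + c1v + cls(t2, t3) + cls(t3, n_bins)
          if (obj > best) { best <- obj; best_b <- c(t1, t2, t3) }
        }
      }
    }
  }
  structure(list(thresholds = best_b / n_bins, n_classes = nK,
                 n_bins = as.integer(n_bins)),
            class = "otsu_thresholds")
}

#' @export
print.otsu_thresholds <- function(x, ...) {
  cat(sprintf("Otsu thresholds (N = %d, %d bins): %s\n", x$n_classes,
              x$n_bins, paste(format(x$thresholds), collapse = ", ")))
  invisible(x)
}

#' Asymmetric half-widths from Otsu thresholds
#'
#' Converts the histogram thresholds and the foreground constant c1 into the
#' half-widths (gamma1, gamma2) of the asymmetric background penalty: the
#' band \[c1 - gamma1, c1 + gamma2\] spans the histogram class containing c1.
#' Three cases: (i) c1 between two thresholds gives the enclosing interval;
#' (ii) c1 below the first threshold gives (c1, T1 - c1); (iii) c1 above the
#' last gives (c1 - T_last, 1 - c1). Zero widths are floored at `gamma_min`.
#'
#' @param c1 foreground intensity in \[0,1\].
#' @param T an `"otsu_thresholds"` object (or numeric vector of thresholds).
#' @param gamma_min strictly positive floor for either width (default 1e-3).
#' @return named numeric vector c(gamma1, gamma2).
#' @export
gamma_from_thresholds <- function(c1, T, gamma_min = 1e-3) {
  th <- if (inherits(T, "otsu_thresholds")) T$thresholds else as.numeric(T)
  if (is.unsorted(th, strictly = TRUE)) stop("thresholds must be increasing")
  if (c1 < 0 || c1 > 1) stop("'c1' must lie in [0,1]")
  nT <- length(th)
  # prefer case (i) when c1 sits exactly on a threshold shared by two cases
  i_upper <- which(th > c1)[1L]
  if (is.na(i_upper) && any(th == c1) && which(th == c1) > 1L)
    i_upper <- which(th == c1)  # c1 on the last threshold with one below: case (i)
  if (!is.na(i_upper) && i_upper > 1L) {
    g <- c(c1 - th[i_upper - 1L], th[i_upper] - c1)          # case (i)
  } else if (!is.na(i_upper)) {
    g <- c(c1, th[1L] - c1)                                  # case (ii)
  } else {
    g <- c(c1 - th[nT], 1 - c1)                              # case (iii)
  }
  g <- pmax(g, gamma_min)
  names(g) <- c("gamma1", "gamma2")
  g
}
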