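#' Tanimoto (Jaccard) coefficient
#'
#' |pred & gt| / |pred | gt| between two binary masks. 1 means identical
#' foregrounds; 0 means disjoint. If both masks are empty the two
#' segmentations agree that there is no object, and the value is defined as
#' 1; an empty prediction against a non-empty truth scores 0.
#'
#' @param pred,gt logical matrices of the same shape.
#' @return scalar in \[0, 1\].
#' @export
tanimoto <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("mask shapes differ")
  pred <- pred & TRUE; gt <- gt & TRUE
  uni <- sum(pred | gt)
  if (uni == 0L) return(1)
  sum(pred & gt) / uni
}

#' The benchmark parameter grid
#'
#' Integer weights 1..10 plus every fifth value from 15 to 50, used for both
#' the data weight lambda and the selection weight theta in robustness
#' sweeps.
#' @return numeric vector.
#' @export
default_sweep_grid <- function() c(1:10, seq(15, 50, by = 5))

#' Accuracy sweep over (lambda, theta)
#'
#' Solves the segmentation at every pair of the two weight grids with fixed
#' markers and records the Tanimoto coefficient against the ground truth.
#' Individual failed solves are recorded as TC = 0 and flagged; the sweep
#' continues.
#'
#' @param z image matrix in \[0,1\].
#' @param markers a `"marker_region"` (or k x 2 point matrix).
#' @param gt logical ground-truth mask.
#' @param model fitting model id passed to [selseg()].
#' @param lambda_grid,theta_grid weight grids (default [default_sweep_grid()]).
#' @param ... further arguments to [selseg()].
#' @return list of class `"sweep_result"`: `tc` (|lambda| x |theta| matrix),
#'   `failed` (logical matrix), the grids and the model id.
#' @export
parameter_sweep <- function(z, markers, gt, model = "pm",
                            lambda_grid = default_sweep_grid(),
                            theta_grid = default_sweep_grid(), ...) {
  if (!length(lambda_grid) || !length(theta_grid)) stop("empty grid")
  P <- if (inherits(markers, "marker_region")) markers else
    polygon_region(markers, dim(z))
  tc <- matrix(NA_real_, length(lambda_grid), length(theta_grid),
               dimnames = list(lambda = lambda_grid, theta = theta_grid))
  failed <- matrix(FALSE, length(lambda_grid), length(theta_grid))
  for (i in seq_along(lambda_grid)) {
    for (j in seq_along(theta_grid)) {
      fit <- tryCatch(
        selseg(z, P, model = model, lambda = lambda_grid[i],
               theta = theta_grid[j], keep_trace = FALSE, ...),
        error = function(e) NULL)
      if (is.null(fit)) {
        tc[i, j] <- 0; failed[i, j] <- TRUE
      } else {
        tc[i, j] <- tanimoto(fit$mask, gt)
      }
    }
  }
  structure(list(tc = tc, failed = failed, lambda_grid = lambda_grid,
                 theta_grid = theta_grid, model = model),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Parameter sweep (%s): %d x %d grid, TC in [%.3f, %.3f], %d failures\n",
              x$model, length(x$lambda_grid), length(x$theta_grid),
              min(x$tc), max(x$tc), sum(x$failed)))
  invisible(x)
}

#' Long-form data frame of a sweep
#' @param x a `"sweep_result"`.
#' @param ... unused.
#' @export
as.data.frame.sweep_result <- function(x, ...) {
  data.frame(model = x$model,
             lambda = rep(x$lambda_grid, times = length(x$theta_grid)),
             theta = rep(x$theta_grid, each = length(x$lambda_grid)),
             tc = as.vector(x$tc), failed = as.vector(x$failed))
}

#' Randomised-marker robustness study
#'
#' Measures how much the segmentation depends on the user input: draws
#' `n_trials` random triangles of `k_markers` points uniformly from the
#' interior of the target, solves with fixed (lambda, theta), and returns
#' the sample of Tanimoto coefficients. The drawing assumptions mirror
#' minimal plausible input: all points inside the target, only 3 markers.
#'
#' @param z image matrix in \[0,1\].
#' @param gt logical ground-truth mask (also the marker-sampling region).
#' @param model fitting model id.
#' @param n_trials number of random marker sets.
#' @param k_markers points per set (default 3).
#' @param lambda,theta fixed weights for all trials.
#' @param seed RNG seed; the whole study is reproducible from it.
#' @param min_depth markers are drawn from pixels at least this deep inside
#'   the target (default 1.5 px), keeping triangles strictly interior.
#' @param ... further arguments to [selseg()].
#' @return list of class `"marker_study"`: `tc` (vector), `summary`
#'   (mean/quartiles/IQR fences), `n_skipped`.
#' @export
randomized_marker_study <- function(z, gt, model = "pm", n_trials = 100,
                                    k_markers = 3, lambda = 5, theta = 5,
                                    seed = 1, min_depth = 1.5, ...) {
  d <- .interior_depth(gt)
  interior_idx <- which(gt & d >= min_depth)
  if (length(interior_idx) < k_markers)
    stop("target interior too small for the requested markers")
  set.seed(seed)
  shape <- dim(z)
  tc <- rep(NA_real_, n_trials)
  skipped <- 0L
  for (i in seq_len(n_trials)) {
    P <- .random_marker_triangle(gt, interior_idx, shape, k_markers)
    if (is.null(P)) {
      skipped <- skipped + 1L
      message(sprintf("trial %d: no valid marker polygon after retries; skipped", i))
      next
    }
    fit <- selseg(z, P, model = model, lambda = lambda, theta = theta,
                  keep_trace = FALSE, ...)
    tc[i] <- tanimoto(fit$mask, gt)
  }
  tc <- tc[!is.na(tc)]
  q <- stats::quantile(tc, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  structure(list(
    tc = tc,
    summary = c(mean = mean(tc), q1 = q[1], median = q[2], q3 = q[3],
                lower_fence = q[1] - 1.5 * iqr, upper_fence = q[3] + 1.5 * iqr),
    n_skipped = skipped, model = model, lambda = lambda, theta = theta),
    class = "marker_study")
}

#' @export
print.marker_study <- function(x, ...) {
  cat(sprintf(
    "Randomised-marker study (%s, lambda = %g, theta = %g): %d trials\n",
    x$model, x$lambda, x$theta, length(x$tc)))
  cat(sprintf("  mean TC %.4f, median %.4f, IQR [%.4f, %.4f], min %.4f\n",
              x$summary["mean"], x$summary["median"], x$summary["q1"],
              x$summary["q3"], min(x$tc)))
  invisible(x)
}

#' Coarse tuning of (lambda, theta) on default markers
#'
#' Convenience grid search used to fix the weights before a robustness
#' study: runs a small sweep with the deterministic default markers and
#' returns the best pair (first in row-major order on ties).
#'
#' @param fixture a `"seg_fixture"`.
#' @param model fitting model id.
#' @param lambda_grid,theta_grid coarse grids (default c(2, 5, 10, 20)).
#' @param marker_seed seed for [default_markers()].
#' @param ... further arguments to [selseg()].
#' @return list with `lambda`, `theta`, `tc`, `sweep`.
#' @export
tune_weights <- function(fixture, model = "pm",
                         lambda_grid = c(2, 5, 10, 20),
                         theta_grid = c(2, 5, 10, 20), marker_seed = 1, ...) {
  P <- default_markers(fixture$gt, seed = marker_seed)
  sw <- parameter_sweep(fixture$image, P, fixture$gt, model = model,
                        lambda_grid = lambda_grid, theta_grid = theta_grid,
                        ...)
  best <- which(sw$tc == max(sw$tc), arr.ind = TRUE)[1, ]
  list(lambda = lambda_grid[best[1]], theta = theta_grid[best[2]],
       tc = max(sw$tc), sweep = sw)
}
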