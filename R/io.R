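# Image, mask and marker I/O. Greyscale PNG/TIFF in; masks as 0/255 PNG or a
# plain-text run-length format convenient for text-only fixtures; distance
# and fitting fields as 32-bit float TIFF for inspection.

#' Read a greyscale image
#'
#' Reads an 8/16-bit PNG or TIFF, averages channels if needed, and rescales
#' intensities to \[0,1\] with [normalize_image()].
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param normalize rescale to \[0,1\] (default TRUE).
#' @return numeric matrix.
#' @export
read_image <- function(path, normalize = TRUE) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext))
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                       c(1, 2), mean)
  if (normalize) normalize_image(a) else a
}

#' Write a binary mask as a black/white PNG
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a 0/255 (or 0/1) PNG mask
#' @param path input path.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a > 0.5
}

#' Write a scalar field as 32-bit float TIFF
#' @param x numeric matrix (any range; stored as float).
#' @param path output path.
#' @export
write_field_tiff <- function(x, path) {
  tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Plain-text run-length mask format
#'
#' Line 1: "nrow ncol"; following lines: "value length" runs in column-major
#' order. Text-only and diffable, used for shipping small fixture masks.
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_rle <- function(mask, path) {
  r <- rle(as.integer(mask))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mask), ncol(mask)), con)
  writeLines(sprintf("%d %d", r$values, r$lengths), con)
  invisible(path)
}

#' @rdname write_mask_rle
#' @export
read_mask_rle <- function(path) {
  lines <- readLines(path)
  shape <- as.integer(strsplit(lines[1], " ")[[1]])
  runs <- do.call(rbind, lapply(strsplit(lines[-1], " "), as.integer))
  v <- inverse.rle(list(values = runs[, 1], lengths = runs[, 2]))
  matrix(v == 1L, shape[1], shape[2])
}

#' Read marker points from CSV
#'
#' Expects two columns, row and col (header optional), 1-based pixel
#' coordinates in input order.
#'
#' @param path CSV path.
#' @return k x 2 numeric matrix.
#' @export
read_markers_csv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", first)
  m <- as.matrix(utils::read.csv(path, header = header))
  storage.mode(m) <- "numeric"
  colnames(m) <- c("row", "col")
  m
}

#' Run the full segmentation pipeline on files or a fixture
#'
#' Loads/normalises the image (or generates a named synthetic fixture),
#' resolves markers, fits [selseg()], writes the mask and an optional JSON
#' report with the resolved parameters, convergence information and the
#' Tanimoto coefficient when a ground truth is available.
#'
#' @param image path to a PNG/TIFF image, a numeric matrix, or a
#'   `"seg_fixture"`.
#' @param markers path to a marker CSV, a k x 2 matrix, or NULL to use
#'   [default_markers()] (fixtures only).
#' @param gt optional ground-truth mask (path or logical matrix); for a
#'   fixture the bundled truth is used automatically.
#' @param out_mask,out_report optional output paths (PNG mask, JSON report).
#' @param ... passed to [selseg()] (model, lambda, theta, ...).
#' @return the `"selseg"` fit, invisibly with `report` attached.
#' @export
run_segmentation <- function(image, markers = NULL, gt = NULL,
                             out_mask = NULL, out_report = NULL, ...) {
  if (inherits(image, "seg_fixture")) {
    z <- image$image
    if (is.null(gt)) gt <- image$gt
    if (is.null(markers)) markers <- default_markers(image$gt)
  } else if (is.character(image)) {
    z <- read_image(image)
  } else z <- image
  if (is.character(markers)) markers <- read_markers_csv(markers)
  if (is.null(markers)) stop("no marker source given")
  if (is.character(gt)) gt <- read_mask_png(gt)
  fit <- selseg(z, markers, gt = gt, ...)
  report <- list(model = fit$model, lambda = fit$lambda, theta = fit$theta,
                 c1 = fit$c1, gammas = fit$gammas, alpha = fit$alpha,
                 iterations = fit$iterations, converged = fit$converged,
                 foreground_pixels = sum(fit$mask))
  if (!is.null(fit$tc)) report$tc <- fit$tc
  if (!is.null(out_mask)) write_mask_png(fit$mask, out_mask)
  if (!is.null(out_report))
    jsonlite::write_json(report, out_report, auto_unbox = TRUE, digits = NA)
  fit$report <- report
  invisible(fit)
}
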