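#' Image containers
#'
#' Light S3 wrappers around numeric matrices that carry the calibration a
#' downstream analysis needs. The matrix convention is `values[row, col]`
#' with the origin at the top-left; the geometric centre of an N x N grid is
#' at row `(N + 1) / 2`, column `(N + 1) / 2` (1-based).
#'
#' * `micrograph()` — a real-space intensity grid with its pixel size in
#'   Angstrom per pixel (3.21 A/px is the acquisition default for the
#'   sheet-aggregate area data).
#' * `diffraction_image()` — a square reciprocal-space intensity grid whose
#'   calibration is the Nyquist spatial frequency at the detector edge;
#'   `q_per_pixel = nyquist_q / (N / 2)`.
#' * `label_mask()` — a non-negative integer grid aligned to a micrograph;
#'   0 is background and each positive label is one aggregate.
#'
#' @param values Numeric matrix of intensities (integer matrix for masks).
#' @param pixel_size Pixel size in Angstrom per pixel.
#' @param nyquist_q Spatial frequency in reciprocal Angstrom at the detector
#'   edge (half the image side away from the centre).
#' @param metadata Named list of free-form acquisition metadata (defocus,
#'   dose, camera distance, aperture, ...). Carried along, never interpreted.
#' @return An object of class `capsheet_micrograph`, `capsheet_diffraction`,
#'   or `capsheet_mask`; all are numeric matrices with attributes.
#' @examples
#' m <- micrograph(matrix(rnorm(64), 8), pixel_size = 3.21)
#' pixel_size(m)
#' @export
micrograph <- function(values, pixel_size = 3.21, metadata = list()) {
  values <- as_image_matrix(values)
  check_number(pixel_size, "pixel_size", lower = .Machine$double.xmin)
  structure(values,
    pixel_size = pixel_size, metadata = metadata,
    class = c("capsheet_micrograph", "matrix", "array")
  )
}

#' @rdname micrograph
#' @export
diffraction_image <- function(values, nyquist_q = 1.75, metadata = list()) {
  values <- as_image_matrix(values)
  if (nrow(values) != ncol(values)) {
    abort("A diffraction image must be square.")
  }
  check_number(nyquist_q, "nyquist_q", lower = .Machine$double.xmin)
  structure(values,
    nyquist_q = nyquist_q, metadata = metadata,
    class = c("capsheet_diffraction", "matrix", "array")
  )
}

#' @rdname micrograph
#' @export
label_mask <- function(values) {
  values <- as_image_matrix(values)
  if (any(values < 0) || any(values != round(values))) {
    abort("A label mask must contain non-negative integer values only.")
  }
  storage.mode(values) <- "integer"
  structure(values, class = c("capsheet_mask", "matrix", "array"))
}

as_image_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0L) {
    abort("`values` must be a non-empty numeric matrix.")
  }
  if (anyNA(values)) abort("`values` must not contain missing values.")
  attributes(values) <- list(dim = dim(values))
  values
}

#' @rdname micrograph
#' @param x An image object.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size")
  if (is.null(ps)) abort("Object carries no pixel size.")
  ps
}

#' @rdname micrograph
#' @export
nyquist_q <- function(x) {
  nq <- attr(x, "nyquist_q")
  if (is.null(nq)) abort("Object carries no Nyquist calibration.")
  nq
}

#' Reciprocal-space calibration of a diffraction image
#'
#' The edge of the detector (half the image side from the centre) maps to
#' the Nyquist spatial frequency, so `q_per_pixel = nyquist_q / (N / 2)`.
#'
#' @param img A `capsheet_diffraction` image, or an image size in pixels.
#' @param nyquist Nyquist spatial frequency (1/Angstrom); taken from `img`
#'   when it is a diffraction image.
#' @return q increment per pixel radius, in 1/Angstrom.
#' @export
q_per_pixel <- function(img, nyquist = NULL) {
  if (inherits(img, "capsheet_diffraction")) {
    n <- nrow(img)
    nyquist <- nyquist %||% nyquist_q(img)
  } else {
    n <- check_number(img, "img", lower = 1, integer = TRUE)
    if (is.null(nyquist)) abort("`nyquist` is required when `img` is a size.")
  }
  nyquist / (n / 2)
}

#' @export
print.capsheet_micrograph <- function(x, ...) {
  cat(sprintf(
    "<micrograph> %d x %d px, %.4g A/px, intensity [%.4g, %.4g]\n",
    nrow(x), ncol(x), pixel_size(x), min(x), max(x)
  ))
  invisible(x)
}

#' @export
print.capsheet_diffraction <- function(x, ...) {
  cat(sprintf(
    "<diffraction image> %d x %d px, Nyquist %.4g 1/A (%.5g 1/A per px)\n",
    nrow(x), ncol(x), nyquist_q(x), q_per_pixel(x)
  ))
  invisible(x)
}

#' @export
print.capsheet_mask <- function(x, ...) {
  labs <- sort(unique(x[x > 0L]))
  cat(sprintf(
    "<label mask> %d x %d px, %d label(s)%s\n",
    nrow(x), ncol(x), length(labs),
    if (length(labs)) paste0(": ", paste(utils::head(labs, 8), collapse = ", "),
      if (length(labs) > 8) ", ..." else ""
    ) else ""
  ))
  invisible(x)
}
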