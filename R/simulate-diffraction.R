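#' Specification for a synthetic LDSAED image pair
#'
#' Describes a radially symmetric low-dose selected-area electron
#' diffraction pattern: a smooth monotone scattering envelope, the two
#' diffuse vitreous-ice rings near 3.71 and 2.15 Angstrom d-spacing that
#' appear in target and background exposures alike, and (target only) an
#' optional broad mineral band whose default centre of 2.85 Angstrom makes
#' it span roughly 2.5-3.2 Angstrom — the signature of the
#' octacalcium-phosphate-like sheet phase.
#'
#' The noise-free radial intensity law is
#' `I(q) = amplitude * exp(-rate * q) * (1 + sum_j a_j * G_j(q))`, with
#' `G_j` a unit-height Gaussian in q centred at `1 / d_j` with s.d.
#' `width_j`; ring and band amplitudes are dimensionless multipliers of the
#' local envelope, so the noiseless target/background ratio is exactly
#' `1 + a_band * G_band(q)`.
#'
#' @param image_size Square detector size in pixels.
#' @param nyquist_q Spatial frequency (1/A) at the detector edge.
#' @param center_offset True beam-centre offset `(row, col)` in pixels from
#'   the geometric image centre.
#' @param background_decay `c(amplitude, rate)` of the envelope
#'   `amplitude * exp(-rate * q)` (counts; rate in Angstrom).
#' @param ice_rings List of `c(d_center, amplitude, width)` triplets
#'   (Angstrom, envelope fraction, 1/Angstrom).
#' @param mineral_band `c(d_center, amplitude, width)` for the broad
#'   mineral band, or `NULL` for a band-free target.
#' @param poisson_noise If `TRUE`, each pixel of each exposure is an
#'   independent Poisson draw with the noise-free intensity as its mean
#'   (detector counting statistics; the true noise law of the camera is not
#'   known, so this is a configurable modelling choice).
#' @param seed Integer seed.
#' @return A list of class `diffraction_spec`.
#' @export
diffraction_spec <- function(image_size = 512,
                             nyquist_q = 1.75,
                             center_offset = c(0, 0),
                             background_decay = c(amplitude = 1000, rate = 4),
                             ice_rings = list(c(3.71, 0.5, 0.02), c(2.15, 0.3, 0.02)),
                             mineral_band = c(2.85, 0.10, 0.022),
                             poisson_noise = FALSE,
                             seed = 1L) {
  check_number(image_size, "image_size", lower = 16, integer = TRUE)
  check_number(nyquist_q, "nyquist_q", lower = .Machine$double.xmin)
  stopifnot(length(center_offset) == 2L, is.numeric(center_offset))
  stopifnot(length(background_decay) == 2L, background_decay[1] > 0)
  check_flag(poisson_noise, "poisson_noise")
  check_number(seed, "seed", integer = TRUE)
  for (ring in ice_rings) {
    stopifnot(length(ring) == 3L, ring[1] > 0, ring[2] >= 0, ring[3] > 0)
  }
  if (!is.null(mineral_band)) {
    stopifnot(length(mineral_band) == 3L, mineral_band[2] >= 0, mineral_band[3] > 0)
    if (mineral_band[1] <= 1 / nyquist_q) {
      abort(sprintf(
        "Mineral band at d = %g A is not representable: q = 1/d must be below Nyquist (%g 1/A).",
        mineral_band[1], nyquist_q
      ))
    }
  }
  structure(
    list(
      image_size = as.integer(image_size), nyquist_q = nyquist_q,
      center_offset = as.numeric(center_offset),
      background_decay = unname(as.numeric(background_decay)),
      ice_rings = ice_rings, mineral_band = mineral_band,
      poisson_noise = poisson_noise, seed = as.integer(seed)
    ),
    class = "diffraction_spec"
  )
}

#' Noise-free radial intensity law of the diffraction generator
#'
#' Evaluates the generative envelope-plus-rings model at spatial
#' frequencies `q`, with or without the mineral band. This is the 1D law
#' the 2D images are built from.
#'
#' @param q Spatial frequencies (1/Angstrom).
#' @param spec A [diffraction_spec()].
#' @param band Include the mineral band term (if the spec carries one)?
#' @return Intensities (counts) at `q`.
#' @export
diffraction_radial_intensity <- function(q, spec, band = TRUE) {
  stopifnot(inherits(spec, "diffraction_spec"))
  env <- spec$background_decay[1] * exp(-spec$background_decay[2] * q)
  rel <- rep(0, length(q))
  for (ring in spec$ice_rings) {
    rel <- rel + ring[2] * exp(-(q - 1 / ring[1])^2 / (2 * ring[3]^2))
  }
  if (band && !is.null(spec$mineral_band)) {
    b <- spec$mineral_band
    rel <- rel + b[2] * exp(-(q - 1 / b[1])^2 / (2 * b[3]^2))
  }
  env * (1 + rel)
}

#' Generate a matched target/background LDSAED exposure pair
#'
#' Renders two radially symmetric diffraction images about the same true
#' beam centre: the target carries the envelope, the vitreous-ice rings and
#' (when configured) the mineral band; the background exposure carries the
#' envelope and ice rings only, emulating the adjacent control region
#' collected next to each aggregate. With Poisson noise off and no band,
#' the two images are identical.
#'
#' @param spec A [diffraction_spec()].
#' @return A list with `target` and `background` ([diffraction_image()]s)
#'   and `truth` (list with `center` = true centre in image coordinates
#'   (row, col), `center_offset`, and `mineral_band`).
#' @examples
#' pair <- simulate_diffraction_pair(diffraction_spec(image_size = 128))
#' pair$truth$center
#' @export
simulate_diffraction_pair <- function(spec) {
  stopifnot(inherits(spec, "diffraction_spec"))
  n <- spec$image_size
  center <- (n + 1) / 2 + spec$center_offset
  qpp <- spec$nyquist_q / (n / 2)
  dist <- sqrt(outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, "+"))
  q <- dist * qpp
  target <- diffraction_radial_intensity(q, spec, band = TRUE)
  background <- diffraction_radial_intensity(q, spec, band = FALSE)
  dim(target) <- dim(background) <- c(n, n)
  if (spec$poisson_noise) {
    with_seed(spec$seed, {
      target <- matrix(rpois(n * n, lambda = target), n, n)
      background <- matrix(rpois(n * n, lambda = background), n, n)
    })
  }
  list(
    target = diffraction_image(target, nyquist_q = spec$nyquist_q),
    background = diffraction_image(background, nyquist_q = spec$nyquist_q),
    truth = list(
      center = center, center_offset = spec$center_offset,
      mineral_band = spec$mineral_band
    )
  )
}
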