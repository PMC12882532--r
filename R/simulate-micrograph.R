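#' Specification for a synthetic aggregate micrograph
#'
#' Describes a square micrograph containing electron-dense sheet-aggregates
#' of known footprint over a noisy background. Synthetic aggregates are
#' density-positive (high intensity on low background); real bright-field
#' data with the opposite polarity are handled downstream by the `invert`
#' flag of the area measurement, so the generator and the measurer share
#' one convention.
#'
#' @param image_size Square image side in pixels.
#' @param pixel_size Pixel size in Angstrom per pixel (3.21 matches the
#'   acquisition settings of the area dataset this emulates).
#' @param n_aggregates Number of non-overlapping aggregates to place.
#' @param aggregate_intensity Aggregate plateau intensity above background,
#'   arbitrary density units.
#' @param aggregate_shape `"disk"`, `"ellipse"` or `"fibrous"` (an ellipse
#'   footprint carrying additive sinusoidal striping; the ground-truth area
#'   is the footprint, matching how total thresholded aggregate area — not
#'   individual sheets — is measured).
#' @param radius_range Range (px) the bounding radius is drawn from.
#' @param background_level Constant background offset, density units.
#' @param background_noise_sd Gaussian background noise s.d., density units.
#' @param poisson_noise If `TRUE`, pixel values are Poisson draws with the
#'   noise-free image as the mean (applied before Gaussian noise).
#' @param stripe_amplitude,stripe_period Striping contrast (fraction of
#'   `aggregate_intensity`) and period (px) for `"fibrous"` aggregates.
#' @param seed Integer seed; identical specs give bit-identical output.
#' @return A list of class `micrograph_spec`.
#' @export
micrograph_spec <- function(image_size = 256,
                            pixel_size = 3.21,
                            n_aggregates = 3,
                            aggregate_intensity = 100,
                            aggregate_shape = c("disk", "ellipse", "fibrous"),
                            radius_range = c(8, 16),
                            background_level = 0,
                            background_noise_sd = 0,
                            poisson_noise = FALSE,
                            stripe_amplitude = 0.3,
                            stripe_period = 6,
                            seed = 1L) {
  check_number(image_size, "image_size", lower = 8, integer = TRUE)
  check_number(pixel_size, "pixel_size", lower = .Machine$double.xmin)
  check_number(n_aggregates, "n_aggregates", lower = 0, integer = TRUE)
  check_number(aggregate_intensity, "aggregate_intensity", lower = 0)
  check_number(background_noise_sd, "background_noise_sd", lower = 0)
  check_number(background_level, "background_level", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  check_flag(poisson_noise, "poisson_noise")
  stopifnot(length(radius_range) == 2L, all(radius_range > 0),
            radius_range[1] <= radius_range[2])
  structure(
    list(
      image_size = as.integer(image_size), pixel_size = pixel_size,
      n_aggregates = as.integer(n_aggregates),
      aggregate_intensity = aggregate_intensity,
      aggregate_shape = match.arg(aggregate_shape),
      radius_range = as.numeric(radius_range),
      background_level = background_level,
      background_noise_sd = background_noise_sd,
      poisson_noise = poisson_noise,
      stripe_amplitude = stripe_amplitude,
      stripe_period = stripe_period,
      seed = as.integer(seed)
    ),
    class = "micrograph_spec"
  )
}

#' Generate a ground-truthed synthetic aggregate micrograph
#'
#' Places non-overlapping aggregates of known footprint, rasterises them at
#' elevated intensity over the background, applies the configured noise, and
#' returns the image together with the exact footprint label mask and a
#' ground-truth table. The true area of aggregate k is
#' `pixel_count_k * (pixel_size / 10)^2` nm^2.
#'
#' @param spec A [micrograph_spec()].
#' @return A list with elements `image` ([micrograph()]), `mask`
#'   ([label_mask()] of exact footprints) and `truth` (tibble with
#'   `aggregate_id`, `shape`, `center_row`, `center_col`, `radius_px`,
#'   `pixel_count`, `area_nm2`).
#' @examples
#' sim <- simulate_micrograph(micrograph_spec(n_aggregates = 2, seed = 7))
#' sim$truth
#' @export
simulate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "micrograph_spec"))
  n <- spec$image_size
  with_seed(spec$seed, {
    placements <- place_aggregates(spec)
    signal <- matrix(0, n, n)
    mask <- matrix(0L, n, n)
    for (p in placements) {
      idx <- rasterize_footprint(p, n)
      mask[idx] <- p$id
      signal[idx] <- spec$aggregate_intensity
      if (spec$aggregate_shape == "fibrous" && spec$stripe_amplitude > 0) {
        rc <- arrayInd(idx, c(n, n))
        phase <- (rc[, 1] - p$row) * cos(p$stripe_angle) +
          (rc[, 2] - p$col) * sin(p$stripe_angle)
        stripes <- spec$stripe_amplitude * spec$aggregate_intensity *
          sin(2 * pi * phase / spec$stripe_period)
        signal[idx] <- pmax(signal[idx] + stripes, 0)
      }
    }
    img <- signal + spec$background_level
    if (spec$poisson_noise) {
      img <- matrix(rpois(n * n, lambda = img), n, n)
    }
    if (spec$background_noise_sd > 0) {
      img <- img + matrix(rnorm(n * n, sd = spec$background_noise_sd), n, n)
    }
    counts <- tabulate(mask[mask > 0L], nbins = max(0L, spec$n_aggregates))
    truth <- tibble(
      aggregate_id = vapply(placements, `[[`, integer(1), "id"),
      shape = spec$aggregate_shape,
      center_row = vapply(placements, `[[`, numeric(1), "row"),
      center_col = vapply(placements, `[[`, numeric(1), "col"),
      radius_px = vapply(placements, `[[`, numeric(1), "radius"),
      pixel_count = if (length(placements)) counts[seq_along(placements)] else integer(0),
      area_nm2 = NA_real_
    )
    truth$area_nm2 <- truth$pixel_count * (spec$pixel_size / 10)^2
    list(
      image = micrograph(img, pixel_size = spec$pixel_size),
      mask = label_mask(mask),
      truth = truth
    )
  })
}

# Rejection-sample non-overlapping centres; bounding radii must not touch.
place_aggregates <- function(spec) {
  if (spec$n_aggregates == 0L) return(list())
  n <- spec$image_size
  placements <- list()
  tries <- 0L
  max_tries <- 200L * spec$n_aggregates
  while (length(placements) < spec$n_aggregates) {
    if (tries >= max_tries) {
      abort(sprintf(
        "Could not place %d non-overlapping aggregates of radius %g-%g in a %d px image.",
        spec$n_aggregates, spec$radius_range[1], spec$radius_range[2], n
      ))
    }
    tries <- tries + 1L
    radius <- runif(1, spec$radius_range[1], spec$radius_range[2])
    if (2 * radius + 2 > n) {
      abort(sprintf("Aggregate radius %g does not fit in a %d px image.", radius, n))
    }
    row <- runif(1, radius + 1, n - radius)
    col <- runif(1, radius + 1, n - radius)
    clear <- all(vapply(placements, function(p) {
      sqrt((p$row - row)^2 + (p$col - col)^2) > p$radius + radius + 2
    }, logical(1)))
    if (!clear) next
    placements[[length(placements) + 1L]] <- list(
      id = length(placements) + 1L, row = row, col = col, radius = radius,
      aspect = if (spec$aggregate_shape == "disk") 1 else runif(1, 0.4, 0.8),
      angle = runif(1, 0, pi),
      stripe_angle = runif(1, 0, pi)
    )
  }
  placements
}

# Linear indices of the footprint pixels (disk or rotated ellipse inequality).
rasterize_footprint <- function(p, n) {
  lo_r <- max(1L, floor(p$row - p$radius)); hi_r <- min(n, ceiling(p$row + p$radius))
  lo_c <- max(1L, floor(p$col - p$radius)); hi_c <- min(n, ceiling(p$col + p$radius))
  rr <- lo_r:hi_r
  cc <- lo_c:hi_c
  dr <- outer(rr - p$row, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - p$col)
  a <- p$radius
  b <- p$radius * p$aspect
  u <- (dr * cos(p$angle) + dc * sin(p$angle)) / a
  v <- (-dr * sin(p$angle) + dc * cos(p$angle)) / b
  inside <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  (lo_c - 1L + inside[, 2] - 1L) * n + (lo_r - 1L + inside[, 1])
}

#' Dilate every label of a mask by a disk
#'
#' Grows each labelled footprint outward by `radius` pixels (Euclidean
#' disk), assigning contested pixels to the nearest label. Area measurement
#' mirrors manual mask drawing, where the region of interest is a loose
#' boundary containing the aggregate *and* surrounding background — the
#' adaptive threshold then separates the two. Ground-truth footprint masks
#' are therefore dilated before measurement in realistic (noisy) settings.
#'
#' @param mask A [label_mask()].
#' @param radius Dilation radius in pixels (0 returns the mask unchanged).
#' @return A [label_mask()] of the same shape.
#' @export
dilate_labels <- function(mask, radius) {
  stopifnot(inherits(mask, "capsheet_mask"))
  check_number(radius, "radius", lower = 0)
  if (radius == 0) return(mask)
  n_r <- nrow(mask)
  n_c <- ncol(mask)
  out <- matrix(0L, n_r, n_c)
  best <- matrix(Inf, n_r, n_c)
  for (lab in sort(unique(mask[mask > 0L]))) {
    idx <- which(mask == lab, arr.ind = TRUE)
    lo_r <- max(1L, min(idx[, 1]) - ceiling(radius))
    hi_r <- min(n_r, max(idx[, 1]) + ceiling(radius))
    lo_c <- max(1L, min(idx[, 2]) - ceiling(radius))
    hi_c <- min(n_c, max(idx[, 2]) + ceiling(radius))
    rr <- lo_r:hi_r
    cc <- lo_c:hi_c
    sub_mask <- mask[rr, cc, drop = FALSE] == lab
    # distance to the label is governed by its boundary pixels (4-connectivity)
    inside <- matrix(FALSE, n_r + 2L, n_c + 2L)
    inside[cbind(idx[, 1] + 1L, idx[, 2] + 1L)] <- TRUE
    on_boundary <- !(inside[cbind(idx[, 1], idx[, 2] + 1L)] &
                       inside[cbind(idx[, 1] + 2L, idx[, 2] + 1L)] &
                       inside[cbind(idx[, 1] + 1L, idx[, 2])] &
                       inside[cbind(idx[, 1] + 1L, idx[, 2] + 2L)])
    bnd <- idx[on_boundary, , drop = FALSE]
    d2 <- matrix(Inf, length(rr), length(cc))
    for (k in seq_len(nrow(bnd))) {
      cand <- outer((rr - bnd[k, 1])^2, (cc - bnd[k, 2])^2, "+")
      d2 <- pmin(d2, cand)
    }
    d2[sub_mask] <- 0
    sel <- d2 <= radius^2
    sub_best <- best[rr, cc]
    take <- sel & (d2 < sub_best)
    sub_out <- out[rr, cc]
    sub_out[take] <- lab
    sub_best[take] <- d2[take]
    out[rr, cc] <- sub_out
    best[rr, cc] <- sub_best
  }
  label_mask(out)
}
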