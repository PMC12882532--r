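#' Adaptive region threshold for aggregate segmentation
#'
#' Computes the per-region binary threshold
#' `T = (max - min) - kappa * sigma`, where `max`, `min` and `sigma` are the
#' maximum, minimum and population standard deviation of the region's pixel
#' values and `kappa` defaults to 1.5. `T` is a *range-based level*: a pixel
#' passes when its min-shifted value satisfies `(value - min) >= T`, which
#' makes the rule invariant to any constant intensity offset. Because the
#' region statistics are recomputed per aggregate, two aggregates in the
#' same image each get their own threshold. `T` can be negative (then every
#' pixel passes) and is 0 for a constant region (again every pixel passes).
#'
#' @param region_values Numeric vector of the region's pixel intensities.
#' @param kappa Non-negative multiplier of the standard deviation.
#' @param invert If `TRUE`, values are negated before all computations —
#'   use for bright-field-polarity data where aggregates are dark.
#' @return The threshold `T` in density units (on the possibly negated
#'   scale).
#' @examples
#' region_threshold(c(0, 0, 100, 100)) # 100 - 1.5 * 50 = 25
#' @export
region_threshold <- function(region_values, kappa = 1.5, invert = FALSE) {
  if (length(region_values) == 0L) abort("Region is empty; cannot threshold.")
  if (!is.numeric(region_values) || anyNA(region_values)) {
    abort("`region_values` must be numeric with no missing values.")
  }
  check_number(kappa, "kappa", lower = 0)
  check_flag(invert, "invert")
  v <- if (invert) -as.double(region_values) else as.double(region_values)
  sigma <- sqrt(mean((v - mean(v))^2)) # population s.d.
  (max(v) - min(v)) - kappa * sigma
}

#' Measure one aggregate's thresholded area
#'
#' Restricts the image to the pixels of one mask label, applies
#' [region_threshold()] to that region, counts the pixels whose min-shifted
#' value reaches the threshold (ties pass; all components are counted), and
#' converts the count to nm^2 with `count * (pixel_size / 10)^2`. A
#' constant region yields `T = 0` and counts every pixel, with a warning.
#'
#' @param image A [micrograph()].
#' @param mask A [label_mask()] of the same shape.
#' @param aggregate_id Positive integer label to measure.
#' @param kappa,invert Passed to [region_threshold()].
#' @param condition Condition label recorded in the output.
#' @return One-row tibble: `aggregate_id`, `condition`,
#'   `region_pixel_count`, `threshold`, `above_threshold_pixels`,
#'   `area_nm2`.
#' @export
measure_aggregate_area <- function(image, mask, aggregate_id,
                                   kappa = 1.5, invert = FALSE,
                                   condition = NA_character_) {
  stopifnot(inherits(image, "capsheet_micrograph"), inherits(mask, "capsheet_mask"))
  if (!all(dim(image) == dim(mask))) {
    abort("Image and mask dimensions differ; they must be aligned.")
  }
  sel <- mask == aggregate_id
  if (!any(sel)) {
    abort(sprintf("Label %s is not present in the mask.", aggregate_id))
  }
  v <- as.double(unclass(image)[sel])
  if (invert) v <- -v
  thr <- region_threshold(v, kappa = kappa, invert = FALSE)
  if (max(v) == min(v)) {
    warn(sprintf(
      "Region %s is constant: threshold 0 keeps all %d pixels.",
      aggregate_id, length(v)
    ))
  }
  passing <- sum((v - min(v)) >= thr)
  tibble(
    aggregate_id = as.integer(aggregate_id),
    condition = condition,
    region_pixel_count = length(v),
    threshold = thr,
    above_threshold_pixels = as.integer(passing),
    area_nm2 = passing * (pixel_size(image) / 10)^2
  )
}

#' Measure every aggregate in a mask
#'
#' Applies [measure_aggregate_area()] to each distinct positive label, each
#' with its own independently computed threshold, and binds the records
#' into an area table.
#'
#' @inheritParams measure_aggregate_area
#' @return A tibble with one row per label (empty, with a warning, for an
#'   empty mask), columns as in [measure_aggregate_area()].
#' @examples
#' sim <- simulate_micrograph(micrograph_spec(n_aggregates = 2, seed = 3))
#' measure_aggregates(sim$image, sim$mask, condition = "demo")
#' @export
measure_aggregates <- function(image, mask, kappa = 1.5, invert = FALSE,
                               condition = NA_character_) {
  stopifnot(inherits(mask, "capsheet_mask"))
  labels <- sort(unique(mask[mask > 0L]))
  if (length(labels) == 0L) {
    warn("Mask contains no labels; returning an empty area table.")
    return(tibble(
      aggregate_id = integer(), condition = character(),
      region_pixel_count = integer(), threshold = double(),
      above_threshold_pixels = integer(), area_nm2 = double()
    ))
  }
  purrr::map_dfr(labels, function(lab) {
    measure_aggregate_area(image, mask, lab,
      kappa = kappa, invert = invert, condition = condition
    )
  })
}
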