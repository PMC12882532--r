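#' Read pipeline images from MRC2014 or TIFF files
#'
#' Dispatches on the file extension (`.mrc`/`.mrcs`/`.map` or
#' `.tif`/`.tiff`) and on `kind`, returning the matching container.
#' Calibration precedence is file header, then the explicit argument, then
#' the package default (3.21 A/px for micrographs, 1.75 1/A Nyquist for
#' diffraction images) with a warning when the default is used — TIFF files
#' and diffraction MRC headers carry no usable calibration, so the fallback
#' is routine for them.
#'
#' @param path Path to an MRC2014 or TIFF file.
#' @param kind One of `"micrograph"`, `"diffraction"`, `"mask"`.
#' @param pixel_size Pixel size (A/px) used when the file carries none.
#' @param nyquist Nyquist spatial frequency (1/A) for diffraction images;
#'   never stored in the file formats handled here.
#' @param metadata Optional named list attached to the returned image.
#' @return A [micrograph()], [diffraction_image()] or [label_mask()].
#' @export
read_image <- function(path,
                       kind = c("micrograph", "diffraction", "mask"),
                       pixel_size = NULL, nyquist = NULL, metadata = list()) {
  kind <- match.arg(kind)
  fmt <- image_format(path)
  if (fmt == "mrc") {
    raw <- read_mrc(path)
    values <- raw$values
    header_ps <- raw$pixel_size
  } else {
    if (kind == "mask") {
      # readTIFF(as.is = TRUE) only yields stored sample values for integer
      # TIFFs; for float TIFFs it bit-casts, so detect the sample format by
      # comparing against the normalised read
      raw_vals <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
      norm_vals <- tiff::readTIFF(path)
      bits <- attr(raw_vals, "bits.per.sample") %||% 8L
      is_integer_tiff <-
        max(abs(raw_vals - norm_vals * (2^bits - 1))) < 0.5
      values <- if (is_integer_tiff) raw_vals else norm_vals
    } else {
      values <- tiff::readTIFF(path)
    }
    if (length(dim(values)) == 3L) values <- values[, , 1L] # first channel
    header_ps <- NA_real_
  }

  if (kind == "mask") {
    if (any(values != round(values))) {
      abort(sprintf("Mask file %s contains non-integer values.", path))
    }
    return(label_mask(values))
  }

  if (kind == "micrograph") {
    ps <- resolve_calibration(header_ps, pixel_size, 3.21, "pixel size (A/px)", path)
    micrograph(values, pixel_size = ps, metadata = metadata)
  } else {
    nq <- resolve_calibration(NA_real_, nyquist, 1.75, "Nyquist q (1/A)", path)
    diffraction_image(values, nyquist_q = nq, metadata = metadata)
  }
}

resolve_calibration <- function(header, arg, default, what, path) {
  if (is.finite(header) && header > 0) return(header)
  if (!is.null(arg)) return(arg)
  warn(sprintf(
    "%s: no %s in file or arguments; using default %g.", path, what, default
  ))
  default
}

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "mrcs", "map")) return("mrc")
  if (ext %in% c("tif", "tiff")) return("tiff")
  abort(sprintf("Unsupported image format '.%s' (use MRC2014 or TIFF).", ext))
}

#' Write pipeline images as MRC2014 or TIFF
#'
#' Real-valued images go to MRC2014 mode 2 (float32, lossless, pixel size in
#' the header) or — only when all values already lie in `[0, 1]` — to 32-bit
#' float TIFF, which cannot represent other ranges losslessly. Label masks
#' are written as integer data (MRC mode 1 or 16-bit TIFF); requesting a
#' float mode for a mask is refused.
#'
#' @param img A [micrograph()], [diffraction_image()] or [label_mask()].
#' @param path Destination path; the extension picks the container format.
#' @param mode MRC data mode override; masks must use an integer mode.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, mode = NULL) {
  fmt <- image_format(path)
  is_mask <- inherits(img, "capsheet_mask")
  if (is_mask && !is.null(mode) && mode == 2) {
    abort("Refusing to write a label mask in a float mode; labels are integers.")
  }
  values <- unclass(img)
  attributes(values) <- list(dim = dim(values))

  if (fmt == "mrc") {
    ps <- attr(img, "pixel_size") %||% 1
    write_mrc(values, path, pixel_size = ps, mode = mode)
  } else {
    if (is_mask) {
      if (max(values) > 65535L) abort("Mask labels exceed 16-bit TIFF range.")
      tiff::writeTIFF(values / 65535, path, bits.per.sample = 16L, reduce = FALSE)
    } else {
      if (min(values) < 0 || max(values) > 1) {
        abort(paste0(
          "Float TIFF storage is only lossless for values in [0, 1]; ",
          "write this image as MRC2014 instead."
        ))
      }
      tiff::writeTIFF(values, path, bits.per.sample = 32L, reduce = FALSE)
    }
  }
  invisible(path)
}

#' Read and write the pipeline's CSV tables
#'
#' Area tables hold one row per measured aggregate; `condition` and
#' `area_nm2` are required on read and any further columns are preserved.
#' Contingency tables are single-row CSVs with integer columns `a` (first
#' group, marker-positive), `b` (first group, negative), `c` (second group,
#' positive) and `d` (second group, negative).
#'
#' @param path CSV path (UTF-8, comma separated, header row).
#' @param table A tibble (area table) or the result of
#'   [contingency_table()].
#' @return Tibbles; `write_*` return `path` invisibly.
#' @export
read_area_table <- function(path) {
  df <- read_csv_checked(path, required = c("condition", "area_nm2"))
  df$condition <- as.character(df$condition)
  df
}

#' @rdname read_area_table
#' @export
write_area_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_area_table
#' @export
read_contingency_table <- function(path) {
  df <- read_csv_checked(path, required = c("a", "b", "c", "d"))
  contingency_table(df$a[1], df$b[1], df$c[1], df$d[1])
}

#' @rdname read_area_table
#' @export
write_contingency_table <- function(table, path) {
  stopifnot(inherits(table, "capsheet_contingency"))
  utils::write.csv(
    data.frame(a = table$a, b = table$b, c = table$c, d = table$d),
    path,
    row.names = FALSE
  )
  invisible(path)
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("Cannot read CSV %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0L) abort(sprintf("CSV %s contains no data rows.", path))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf(
      "CSV %s is missing required column(s): %s.",
      path, paste(missing, collapse = ", ")
    ))
  }
  as_tibble(df)
}
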