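# Minimal MRC2014 reader/writer (2D images; modes 0 = int8, 1 = int16,
# 2 = float32, 6 = uint16). Data are stored x-fastest; the R matrices used
# throughout the package are [row, col], so the writer emits t(values) and
# the reader fills by row. Pixel size lives in CELLA / MX per the standard.

MRC_HEADER_BYTES <- 1024L

#' Read and write MRC2014 images
#'
#' `write_mrc()` stores a 2D image as a single-section MRC2014 file
#' (float32 mode 2 for real-valued data, int16 mode 1 for integer data such
#' as label masks) with the pixel size recorded in the cell dimensions.
#' `read_mrc()` reads modes 0, 1, 2 and 6 back, recovering values, shape and
#' pixel size exactly for data written by `write_mrc()`.
#'
#' @param values Numeric or integer matrix (`[row, col]`).
#' @param path File path.
#' @param pixel_size Pixel size in Angstrom per pixel, stored in the header.
#' @param mode MRC data mode; `NULL` picks 1 for integer matrices and 2
#'   otherwise. Integer modes refuse non-integer data.
#' @return `read_mrc()` returns a list with `values`, `pixel_size` and
#'   `mode`. `write_mrc()` returns `path` invisibly.
#' @export
write_mrc <- function(values, path, pixel_size = 1, mode = NULL) {
  if (!is.matrix(values) || length(values) == 0L) {
    abort("`values` must be a non-empty matrix.")
  }
  check_number(pixel_size, "pixel_size", lower = .Machine$double.xmin)
  mode <- mode %||% (if (is.integer(values)) 1L else 2L)
  if (!mode %in% c(0L, 1L, 2L, 6L)) {
    abort(sprintf("Unsupported MRC mode %s (supported: 0, 1, 2, 6).", mode))
  }
  if (mode != 2L && any(values != round(values))) {
    abort(sprintf("MRC mode %d is integer-valued; data contain fractions.", mode))
  }
  rng <- switch(as.character(mode),
    "0" = c(-128, 127), "1" = c(-32768, 32767), "6" = c(0, 65535),
    c(-Inf, Inf)
  )
  if (mode != 2L && (min(values) < rng[1] || max(values) > rng[2])) {
    abort(sprintf("Data exceed the range of MRC mode %d.", mode))
  }

  nx <- ncol(values)
  ny <- nrow(values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wi(c(nx, ny, 1L, mode)) # NX NY NZ MODE
  wi(c(0L, 0L, 0L)) # NXSTART..
  wi(c(nx, ny, 1L)) # MX MY MZ
  wf(c(nx * pixel_size, ny * pixel_size, pixel_size)) # CELLA (A)
  wf(c(90, 90, 90)) # CELLB
  wi(c(1L, 2L, 3L)) # MAPC MAPR MAPS
  wf(c(min(values), max(values), mean(values))) # DMIN DMAX DMEAN
  wi(c(0L, 0L)) # ISPG NSYMBT
  writeBin(raw(8L), con) # EXTRA (96..103)
  writeChar("MRCO", con, nchars = 4L, eos = NULL) # EXTTYP
  wi(20140L) # NVERSION
  writeBin(raw(84L), con) # EXTRA (112..195)
  wf(c(0, 0, 0)) # ORIGIN
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # MACHST little-endian
  wf(stats::sd(as.double(values)) * sqrt((length(values) - 1) / length(values)))
  wi(1L) # NLABL
  writeChar(formatC("capsheet", width = -80L), con, nchars = 80L, eos = NULL)
  writeBin(raw(9L * 80L), con)

  data <- as.vector(t(values)) # x fastest
  switch(as.character(mode),
    "0" = writeBin(as.integer(data), con, size = 1L, endian = "little"),
    "1" = writeBin(as.integer(data), con, size = 2L, endian = "little"),
    "2" = writeBin(as.double(data), con, size = 4L, endian = "little"),
    "6" = {
      # uint16 via signed write: map [32768, 65535] onto the negative range
      d <- as.integer(data)
      d <- ifelse(d > 32767L, d - 65536L, d)
      writeBin(d, con, size = 2L, endian = "little")
    }
  )
  invisible(path)
}

#' @rdname write_mrc
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  hdr_raw <- readBin(path, "raw", n = MRC_HEADER_BYTES)
  if (length(hdr_raw) < MRC_HEADER_BYTES) {
    abort(sprintf("Truncated MRC file (header incomplete): %s", path))
  }
  if (rawToChar(hdr_raw[209:212]) != "MAP ") {
    abort(sprintf("Not an MRC2014 file (missing MAP magic): %s", path))
  }
  endian <- if (as.integer(hdr_raw[213]) == 0x11) "big" else "little"
  geti <- function(off) {
    readBin(hdr_raw[(off + 1):(off + 4)], "integer", size = 4L, endian = endian)
  }
  getf <- function(off) {
    readBin(hdr_raw[(off + 1):(off + 4)], "double", size = 4L, endian = endian)
  }
  nx <- geti(0); ny <- geti(4); nz <- geti(8); mode <- geti(12)
  mx <- geti(28)
  xlen <- getf(40)
  if (!mode %in% c(0L, 1L, 2L, 6L)) {
    abort(sprintf("Unsupported MRC mode %d in %s.", mode, path))
  }
  if (nx <= 0 || ny <= 0 || nz != 1L) {
    abort(sprintf("Expected a single 2D section, got %d x %d x %d.", nx, ny, nz))
  }
  pixel_size <- if (mx > 0 && xlen > 0) xlen / mx else NA_real_

  n <- nx * ny
  bytes <- switch(as.character(mode), "0" = 1L, "1" = 2L, "2" = 4L, "6" = 2L)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, MRC_HEADER_BYTES)
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE, endian = endian),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE, endian = endian),
    "2" = readBin(con, "double", n = n, size = 4L, endian = endian),
    "6" = readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = endian)
  )
  if (length(data) < n) {
    abort(sprintf(
      "Truncated MRC file: expected %d values, read %d (%s).",
      n, length(data), path
    ))
  }
  values <- matrix(data, nrow = ny, ncol = nx, byrow = TRUE)
  list(values = values, pixel_size = pixel_size, mode = mode)
}
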