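# Sensor range of the thermal camera the method targets: the raw frame is a
# temperature matrix in degrees Celsius, bounded by the detector's span.
SENSOR_MIN_C <- -20
SENSOR_MAX_C <- 100

#' Validate a thermal frame
#'
#' A thermal frame is a numeric matrix of temperatures in degrees Celsius,
#' indexed `[row = y, col = x]` with the raster origin at the top-left corner
#' (y increases downward).  Values must be finite and inside the sensor range
#' \[-20, 100\] degC, and the frame must be at least 16 x 16 pixels so the
#' downstream ellipse geometry is meaningful.
#'
#' @param values numeric matrix of temperatures (degC).
#' @return the validated matrix, invisibly classed as `thermal_frame`.
#' @export
as_thermal_frame <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("thermal frame must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 16L || ncol(values) < 16L)
    stop("thermal frame must be at least 16x16 pixels", call. = FALSE)
  bad <- which(!is.finite(values) | values < SENSOR_MIN_C | values > SENSOR_MAX_C)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "sensor-range violation: value %.3f at (row %d, col %d) outside [%g, %g] degC",
      values[bad[1L]], rc[1L], rc[2L], SENSOR_MIN_C, SENSOR_MAX_C), call. = FALSE)
  }
  structure(values, class = c("thermal_frame", class(matrix())))
}

#' Read a raw thermal frame
#'
#' Supported containers: `csv` (comma-separated floats in degC, one row per
#' image row, no header), `bin` (a flat little-endian binary array: two int32
#' header words `nrow`, `ncol` followed by row-major float64 temperatures) and
#' `tiff16` (single-channel 16-bit TIFF whose stored integers decode to degC
#' as `value * scale + offset`).
#'
#' @param path file path.
#' @param format one of `"csv"`, `"bin"`, `"tiff16"`.
#' @param scale,offset affine decode for `tiff16` (ignored otherwise).
#' @return a validated [as_thermal_frame()] matrix.
#' @export
read_thermal_frame <- function(path, format = c("csv", "bin", "tiff16"),
                               scale = 0.01, offset = -20) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  values <- switch(format,
    csv = {
      m <- as.matrix(utils::read.csv(path, header = FALSE))
      dimnames(m) <- NULL
      storage.mode(m) <- "double"
      m
    },
    bin = {
      con <- file(path, "rb"); on.exit(close(con))
      dims <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
      if (length(dims) != 2L || any(dims < 1L))
        stop("unparseable binary frame header", call. = FALSE)
      v <- readBin(con, "double", n = dims[1L] * dims[2L], size = 8L,
                   endian = "little")
      if (length(v) != dims[1L] * dims[2L])
        stop("truncated binary frame", call. = FALSE)
      matrix(v, nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
    },
    tiff16 = {
      raw <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
      raw * scale + offset
    })
  if (is.null(dim(values)) || length(dim(values)) != 2L)
    stop("file does not contain a 2-D array", call. = FALSE)
  as_thermal_frame(values)
}

#' Write a thermal frame
#'
#' Inverse of [read_thermal_frame()]; `tiff16` stores
#' `round((T - offset) / scale)` as 16-bit integers.
#'
#' @inheritParams read_thermal_frame
#' @param frame thermal frame matrix.
#' @export
write_thermal_frame <- function(frame, path, format = c("csv", "bin", "tiff16"),
                                scale = 0.01, offset = -20) {
  format <- match.arg(format)
  switch(format,
    csv = utils::write.table(unclass(frame), path, sep = ",",
                             row.names = FALSE, col.names = FALSE),
    bin = {
      con <- file(path, "wb"); on.exit(close(con))
      writeBin(as.integer(dim(frame)), con, size = 4L, endian = "little")
      writeBin(as.double(t(frame)), con, size = 8L, endian = "little")
    },
    tiff16 = {
      stored <- round((unclass(frame) - offset) / scale)
      if (any(stored < 0 | stored > 65535))
        stop("affine encode leaves 16-bit range", call. = FALSE)
      tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16L)
    })
  invisible(path)
}

#' Convert a thermal frame to 8-bit grayscale
#'
#' Linear min-max normalisation to \[0, 255\] with truncation:
#' `P' = floor((P - min) / (max - min) * 255)`, so the coldest pixel maps to 0
#' and the hottest to 255.  The transform only depends on the ordering of
#' temperatures, hence is invariant to affine rescaling of the frame.
#'
#' @param frame thermal frame matrix.
#' @return integer matrix in \[0, 255\] (a gray frame).
#' @export
to_grayscale <- function(frame) {
  rng <- range(frame)
  if (rng[1L] == rng[2L])
    stop("degenerate frame: constant temperature, no head/background contrast",
         call. = FALSE)
  g <- floor((unclass(frame) - rng[1L]) / (rng[2L] - rng[1L]) * 255)
  storage.mode(g) <- "integer"
  g
}

assert_gray <- function(gray) {
  if (!is.matrix(gray) || any(gray < 0L) || any(gray > 255L))
    stop("gray frame must be a matrix with values in [0, 255]", call. = FALSE)
  invisible(gray)
}

assert_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 255L)))
    stop("mask-encoding error: binary mask may only contain 0 and 255",
         call. = FALSE)
  invisible(mask)
}

#' Read / write binary masks as 8-bit PNG
#'
#' Masks are single-channel PNG images whose pixels are exactly 0 or 255; any
#' other value on read is a mask-encoding error.  The round trip
#' `read_mask(write_mask(m))` is the identity.
#'
#' @param mask matrix with entries in \{0, 255\}.
#' @param path file path.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(unclass(mask) / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  m <- round(img * 255)
  if (!all(m %in% c(0, 255)))
    stop("mask-encoding error: PNG contains values other than 0 and 255",
         call. = FALSE)
  storage.mode(m) <- "integer"
  m
}
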