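# File formats: 32-bit float TIFF amplitude/phase pairs, coefficient CSVs,
# and YAML configuration.
#
# Reading float TIFFs goes through tiff::readTIFF, which returns IEEE float
# samples verbatim. Writing is done by a minimal single-strip writer below,
# because phase rasters hold radians in (-pi, pi] and need genuine
# floating-point sample storage.

tiff_entry <- function(con, tag, type, value) {
  writeBin(as.integer(tag), con, size = 2L, endian = "little")
  writeBin(as.integer(type), con, size = 2L, endian = "little")
  writeBin(1L, con, size = 4L, endian = "little")
  if (type == 3L) { # SHORT, left-justified in the 4-byte value field
    writeBin(as.integer(value), con, size = 2L, endian = "little")
    writeBin(raw(2L), con)
  } else { # LONG
    writeBin(as.integer(value), con, size = 4L, endian = "little")
  }
}

#' Write a numeric matrix as a 32-bit float grayscale TIFF
#'
#' Single-strip, little-endian, uncompressed, IEEE float sample format —
#' values are stored verbatim (no `[0, 1]` clamping), so radians survive a
#' round trip exactly at 32-bit precision.
#'
#' @param mat numeric matrix (rows = image rows).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_float_tiff <- function(mat, path) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  h <- nrow(mat)
  w <- ncol(mat)
  nbytes <- 4L * h * w
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(8L + nbytes, con, size = 4L, endian = "little") # IFD offset
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little") # row-major
  entries <- list(
    list(256L, 4L, w),       # ImageWidth
    list(257L, 4L, h),       # ImageLength
    list(258L, 3L, 32L),     # BitsPerSample
    list(259L, 3L, 1L),      # Compression: none
    list(262L, 3L, 1L),      # Photometric: BlackIsZero
    list(273L, 4L, 8L),      # StripOffsets
    list(277L, 3L, 1L),      # SamplesPerPixel
    list(278L, 4L, h),       # RowsPerStrip
    list(279L, 4L, nbytes),  # StripByteCounts
    list(339L, 3L, 3L)       # SampleFormat: IEEE float
  )
  writeBin(length(entries), con, size = 2L, endian = "little")
  for (e in entries) tiff_entry(con, e[[1]], e[[2]], e[[3]])
  writeBin(0L, con, size = 4L, endian = "little") # no next IFD
  invisible(path)
}

#' Write a complex image as an amplitude/phase TIFF pair
#'
#' Produces `<prefix>_amp.tiff` (transmissivity in `[0, 1]`) and
#' `<prefix>_phase.tiff` (radians, wrapped), both 32-bit float.
#'
#' @param image a [complex_image()].
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_complex_image <- function(image, prefix) {
  stopifnot(inherits(image, "complex_image"))
  paths <- paste0(prefix, c("_amp.tiff", "_phase.tiff"))
  write_float_tiff(image$amplitude, paths[1])
  write_float_tiff(image$phase, paths[2])
  invisible(paths)
}

#' Read a complex image from an amplitude/phase TIFF pair
#'
#' Amplitude outside `[0, 1]` is rejected; phase outside `(-pi, pi]` is
#' wrapped with a warning.
#'
#' @param prefix path prefix used by [write_complex_image()].
#' @return a [complex_image()].
#' @export
read_complex_image <- function(prefix) {
  paths <- paste0(prefix, c("_amp.tiff", "_phase.tiff"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    rlang::abort(paste0("missing image component file(s): ",
                        paste(missing, collapse = ", ")),
      class = "holopix_invalid")
  }
  amp <- tiff::readTIFF(paths[1])
  ph <- tiff::readTIFF(paths[2])
  if (!all(dim(amp) == dim(ph))) {
    rlang::abort("amplitude and phase rasters have different shapes.",
      class = "holopix_invalid")
  }
  if (min(amp) < -1e-6 || max(amp) > 1 + 1e-6) {
    rlang::abort("amplitude raster holds values outside [0, 1].",
      class = "holopix_invalid")
  }
  if (min(ph) <= -pi - 1e-6 || max(ph) > pi + 1e-6) {
    rlang::warn("phase raster holds values outside (-pi, pi]; wrapping.")
  }
  complex_image(pmin(pmax(amp, 0), 1), wrap_phase(ph))
}

#' Export a coefficient set as CSV
#'
#' Columns `n`, `u`, `v`, `re`, `im`.
#'
#' @param coeffs an `sph_coeffs` tibble.
#' @param path output CSV file.
#' @return the path, invisibly.
#' @export
write_coefficients <- function(coeffs, path) {
  utils::write.csv(
    data.frame(n = coeffs$order, u = coeffs$u, v = coeffs$v,
               re = Re(coeffs$value), im = Im(coeffs$value)),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a coefficient set from CSV
#'
#' @param path CSV written by [write_coefficients()].
#' @param kind `"binary"` (measured) or `"bipolar"` (corrected).
#' @param side image side the coefficients belong to (optional).
#' @return an `sph_coeffs` tibble.
#' @export
read_coefficients <- function(path, kind = c("binary", "bipolar"),
                              side = NA_integer_) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  coeffs_tibble(df$n, df$u, df$v, complex(real = df$re, imaginary = df$im),
                kind = kind, side = side)
}

config_from_fields <- function(fields, builder, allowed, where) {
  unknown <- setdiff(names(fields), allowed)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown %s key(s): %s", where,
                         paste(unknown, collapse = ", ")),
      class = "holopix_invalid")
  }
  do.call(builder, fields)
}

#' Load acquisition and system configuration from YAML
#'
#' The file may hold `acquisition:` and `system:` sections (either or both;
#' an empty file yields the full default configuration). Unknown keys are
#' rejected with the offending name; values are validated by the
#' constructors (e.g. the Nyquist bound on the beat frequency).
#'
#' @param path YAML file.
#' @return list with `acquisition` ([acquisition_config()]) and `system`
#'   ([system_config()]).
#' @export
load_config <- function(path) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else
    rlang::abort(paste0("config file not found: ", path), class = "holopix_invalid")
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), c("acquisition", "system"))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown top-level config section(s): %s",
                         paste(unknown, collapse = ", ")),
      class = "holopix_invalid")
  }
  list(
    acquisition = config_from_fields(
      cfg$acquisition %||% list(), acquisition_config,
      c("beat_freq", "sample_rate", "refresh_time", "noise_rel",
        "dc_reference", "gain", "seed"), "acquisition"),
    system = config_from_fields(
      cfg$system %||% list(), system_config,
      c("mirror_pitch", "binning", "n_super", "f_front", "f_rear",
        "diag_factor", "anisotropy"), "system")
  )
}
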