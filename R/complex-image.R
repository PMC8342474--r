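#' Wrap an angle into (-pi, pi]
#'
#' Phase is represented wrapped everywhere in the package; nothing ever
#' unwraps. The right-open convention maps -pi to +pi.
#'
#' @param x numeric vector/matrix of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_phase <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

#' Complex-valued object image
#'
#' The object under the illumination patterns is `O(r) = A(r) exp(i phi(r))`:
#' `A` is the spatially varying transmissivity (dimensionless, in `[0, 1]`
#' for physical objects) and `phi` the accumulated phase in radians, stored
#' wrapped to `(-pi, pi]`. Both components are square matrices indexed
#' `[row, col]`, origin top-left.
#'
#' @param amplitude square numeric matrix of transmissivities.
#' @param phase square numeric matrix of phases in radians (same shape);
#'   values outside `(-pi, pi]` are wrapped.
#' @param check_amplitude enforce `amplitude` in `[0, 1]` (the physical
#'   range for a transmissive object). Reconstructions under noise may
#'   slightly exceed 1, so [reconstruct_image()] disables the check.
#' @return a `complex_image` object (list with `amplitude`, `phase`, `side`).
#' @seealso [as_complex_matrix()], [complex_image_from_matrix()]
#' @export
complex_image <- function(amplitude, phase = NULL, check_amplitude = TRUE) {
  if (!is.matrix(amplitude) || nrow(amplitude) != ncol(amplitude)) {
    rlang::abort("`amplitude` must be a square matrix.", class = "holopix_invalid")
  }
  if (is.null(phase)) phase <- matrix(0, nrow(amplitude), ncol(amplitude))
  if (!is.matrix(phase) || !all(dim(phase) == dim(amplitude))) {
    rlang::abort("`phase` must be a matrix with the same shape as `amplitude`.",
      class = "holopix_invalid")
  }
  if (check_amplitude &&
      (min(amplitude) < -1e-9 || max(amplitude) > 1 + 1e-9)) {
    rlang::abort("`amplitude` must lie in [0, 1] for a physical object.",
      class = "holopix_invalid")
  }
  structure(
    list(amplitude = amplitude, phase = wrap_phase(phase), side = nrow(amplitude)),
    class = "complex_image"
  )
}

#' @export
print.complex_image <- function(x, ...) {
  cat(sprintf(
    "<complex_image> %d x %d  amplitude [%.3g, %.3g]  phase [%.3g, %.3g] rad\n",
    x$side, x$side, min(x$amplitude), max(x$amplitude),
    min(x$phase), max(x$phase)
  ))
  invisible(x)
}

#' Convert a complex_image to a complex matrix
#'
#' @param x a `complex_image` (complex matrices pass through unchanged).
#' @return complex matrix `A * exp(i phi)`.
#' @export
as_complex_matrix <- function(x) {
  if (is.matrix(x) && is.complex(x)) return(x)
  if (is.matrix(x) && is.numeric(x)) return(x + 0i)
  if (!inherits(x, "complex_image")) {
    rlang::abort("Expected a complex_image or a complex matrix.",
      class = "holopix_invalid")
  }
  x$amplitude * exp(1i * x$phase)
}

#' Build a complex_image from a complex matrix
#'
#' Amplitude is the modulus, phase the argument wrapped to `(-pi, pi]`.
#'
#' @param z square complex matrix.
#' @param check_amplitude passed to [complex_image()].
#' @return a `complex_image`.
#' @export
complex_image_from_matrix <- function(z, check_amplitude = FALSE) {
  complex_image(Mod(z), wrap_phase(Arg(z)), check_amplitude = check_amplitude)
}

#' Tidy a complex_image into a long tibble
#'
#' One row per pixel with `row`, `col`, `amplitude`, `phase` — the form the
#' ggplot2 raster layers want.
#'
#' @param x a `complex_image`.
#' @param ... unused.
#' @return a tibble with one row per pixel.
#' @method tidy complex_image
#' @export
tidy.complex_image <- function(x, ...) {
  s <- x$side
  tibble::tibble(
    row = rep(seq_len(s), times = s),
    col = rep(seq_len(s), each = s),
    amplitude = as.vector(x$amplitude),
    phase = as.vector(x$phase)
  )
}

#' Plot a component of a complex_image
#'
#' @param object a `complex_image`.
#' @param component `"amplitude"` or `"phase"`.
#' @param ... unused.
#' @return a ggplot raster plot.
#' @method autoplot complex_image
#' @export
autoplot.complex_image <- function(object, component = c("amplitude", "phase"), ...) {
  component <- match.arg(component)
  df <- tidy.complex_image(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data[[component]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = if (component == "phase") "phase (rad)" else "amplitude") +
    ggplot2::theme_minimal()
}
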