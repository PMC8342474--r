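# Image-quality metrics mirroring how holographic reconstructions are
# assessed: 1D profiles across bar elements, phase-step accuracy from ROI
# circular means, contrast-to-noise ratio, and a global-phase-invariant
# complex correlation. All metrics are pure functions.

# resolve an ROI given as list(rows =, cols =) or a logical mask
roi_values <- function(mat, roi) {
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == dim(mat))) {
      rlang::abort("ROI mask shape does not match the image.",
        class = "holopix_invalid")
    }
    v <- mat[roi]
  } else if (is.list(roi) && all(c("rows", "cols") %in% names(roi))) {
    if (min(roi$rows) < 1 || max(roi$rows) > nrow(mat) ||
        min(roi$cols) < 1 || max(roi$cols) > ncol(mat)) {
      rlang::abort("ROI extends outside the image.", class = "holopix_invalid")
    }
    v <- as.vector(mat[roi$rows, roi$cols])
  } else {
    rlang::abort("ROI must be a logical mask or list(rows =, cols =).",
      class = "holopix_invalid")
  }
  if (length(v) == 0) {
    rlang::abort("ROI is empty.", class = "holopix_invalid")
  }
  v
}

component_matrix <- function(image, component) {
  if (inherits(image, "complex_image")) image[[component]] else image
}

#' 1D profile across an image
#'
#' Samples a straight segment from `start_px` to `end_px` (pixel
#' coordinates `c(row, col)`, 1-based) and averages over `width_px` pixels
#' perpendicular to the segment at each step — the standard way bar-target
#' resolution is displayed.
#'
#' @param image a numeric matrix, or a [complex_image()] with `component`.
#' @param start_px,end_px integer-ish `c(row, col)` endpoints, inside the
#'   image.
#' @param width_px averaging width perpendicular to the segment (1 = direct
#'   sampling).
#' @param component which component of a `complex_image` to profile.
#' @return tibble with `step` (pixel index along the segment) and `value`.
#' @export
line_profile <- function(image, start_px, end_px, width_px = 1L,
                         component = c("amplitude", "phase")) {
  mat <- component_matrix(image, match.arg(component))
  ok <- function(p) length(p) == 2 && all(p >= 1) &&
    p[1] <= nrow(mat) && p[2] <= ncol(mat)
  if (!ok(start_px) || !ok(end_px)) {
    rlang::abort("profile endpoints must lie inside the image.",
      class = "holopix_invalid")
  }
  d <- end_px - start_px
  n_steps <- max(abs(d)) + 1L
  dir <- if (all(d == 0)) c(0, 0) else d / max(abs(d))
  perp <- c(-dir[2], dir[1])
  offsets <- seq_len(width_px) - (width_px + 1) / 2
  values <- vapply(seq_len(n_steps) - 1L, function(i) {
    centre <- start_px + i * dir
    pts <- t(vapply(offsets, function(o) round(centre + o * perp), numeric(2)))
    pts[, 1] <- pmin(pmax(pts[, 1], 1), nrow(mat))
    pts[, 2] <- pmin(pmax(pts[, 2], 1), ncol(mat))
    mean(mat[cbind(pts[, 1], pts[, 2])])
  }, numeric(1))
  tibble::tibble(step = seq_len(n_steps), value = values)
}

circular_mean <- function(phase) {
  Arg(mean(exp(1i * phase)))
}

#' Phase-step accuracy
#'
#' Measures the phase difference between a bar ROI and a background ROI as
#' the difference of circular means (robust near the +/-pi wrap), and the
#' absolute error against the nominal step, wrapped to `[0, pi]`. Invariant
#' to a global phase offset on the reconstruction, which a heterodyne
#' measurement cannot fix.
#'
#' @param recon a [complex_image()] (or phase matrix).
#' @param roi_bar,roi_bg disjoint ROIs (logical masks or
#'   `list(rows =, cols =)`).
#' @param nominal nominal phase step in radians.
#' @return tibble with `measured_step` and `error` (radians).
#' @export
phase_error <- function(recon, roi_bar, roi_bg, nominal) {
  ph <- component_matrix(recon, "phase")
  step <- wrap_phase(circular_mean(roi_values(ph, roi_bar)) -
                     circular_mean(roi_values(ph, roi_bg)))
  tibble::tibble(
    measured_step = step,
    error = abs(wrap_phase(step - nominal))
  )
}

#' Contrast-to-noise ratio
#'
#' `(mean(signal ROI) - mean(background ROI)) / sd(background ROI)` — the
#' standard imaging definition.
#'
#' @param image amplitude matrix or [complex_image()].
#' @param roi_sig,roi_bg ROIs; the background needs at least 2 pixels.
#' @return a single number.
#' @export
cnr <- function(image, roi_sig, roi_bg) {
  amp <- component_matrix(image, "amplitude")
  sig <- roi_values(amp, roi_sig)
  bg <- roi_values(amp, roi_bg)
  if (length(bg) < 2) {
    rlang::abort("background ROI needs at least 2 pixels.",
      class = "holopix_invalid")
  }
  s <- stats::sd(bg)
  if (s == 0) {
    rlang::abort("background standard deviation is zero: CNR undefined.",
      class = "holopix_undefined_metric")
  }
  (mean(sig) - mean(bg)) / s
}

#' Global-phase-invariant complex correlation
#'
#' `|sum(a * Conj(b))| / (||a|| * ||b||)` in `[0, 1]`; equals 1 iff the two
#' fields agree up to a global complex scale.
#'
#' @param a,b [complex_image()]s or complex matrices of equal side.
#' @return a number in `[0, 1]`.
#' @export
complex_correlation <- function(a, b) {
  za <- as_complex_matrix(a)
  zb <- as_complex_matrix(b)
  if (!all(dim(za) == dim(zb))) {
    rlang::abort("images have different sides.", class = "holopix_invalid")
  }
  na <- sqrt(sum(Mod(za)^2))
  nb <- sqrt(sum(Mod(zb)^2))
  if (na == 0 || nb == 0) {
    rlang::abort("zero-norm input: correlation undefined.",
      class = "holopix_undefined_metric")
  }
  Mod(sum(za * Conj(zb))) / (na * nb)
}
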