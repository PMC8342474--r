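# Synthetic complex-valued objects: USAF-style three-bar targets, quantitative
# phase-step targets, and smoothed random fields emulating tissue slices.
# Phantoms are noise-free; all stochastic behaviour lives in the forward model.

# logical mask of one three-bar element: bars of width w, length 5w, gap w,
# bounding box 5w x 5w with top-left corner at (row0, col0) (1-based)
three_bar_mask <- function(side, w, orientation = c("vertical", "horizontal"),
                           row0 = 1L, col0 = 1L) {
  orientation <- match.arg(orientation)
  if (w < 1 || w != round(w)) {
    rlang::abort("`bar_width_px` must be a positive integer.",
      class = "holopix_invalid")
  }
  w <- as.integer(w)
  if (row0 < 1 || col0 < 1 || row0 + 5L * w - 1L > side || col0 + 5L * w - 1L > side) {
    rlang::abort("bar element does not fit inside the grid.",
      class = "holopix_invalid")
  }
  mask <- matrix(FALSE, side, side)
  for (b in 0:2) {
    off <- 2L * b * w
    if (orientation == "vertical") {
      rows <- row0:(row0 + 5L * w - 1L)
      cols <- (col0 + off):(col0 + off + w - 1L)
    } else {
      rows <- (row0 + off):(row0 + off + w - 1L)
      cols <- col0:(col0 + 5L * w - 1L)
    }
    mask[rows, cols] <- TRUE
  }
  mask
}

#' USAF-style three-bar amplitude target
#'
#' A positive resolution target: three-bar elements (bar width `w`, length
#' `5 w`, gap `w`) of amplitude 1 on a dark (amplitude 0) background, phase 0
#' everywhere. Elements are laid out left to right with their top-left
#' corners at `(2w, 2w + (i - 1) * 7w)`, orientations cycling through
#' `orientation_mix`.
#'
#' @param side image side in pixels.
#' @param bar_width_px bar width `w` in pixels (resolution element size).
#' @param n_elements number of three-bar elements.
#' @param orientation_mix character vector recycled over elements,
#'   entries `"vertical"` or `"horizontal"`.
#' @return a [complex_image()].
#' @export
bar_target <- function(side, bar_width_px = 4L, n_elements = 1L,
                       orientation_mix = "vertical") {
  amp <- matrix(0, side, side)
  w <- as.integer(bar_width_px)
  for (i in seq_len(n_elements)) {
    ori <- orientation_mix[[(i - 1L) %% length(orientation_mix) + 1L]]
    mask <- three_bar_mask(side, w, ori,
                           row0 = 2L * w, col0 = 2L * w + (i - 1L) * 7L * w)
    amp[mask] <- 1
  }
  complex_image(amp)
}

#' Quantitative phase-step target
#'
#' Uniform transmissivity 1; the phase is `delta_phi` on a centred three-bar
#' element and 0 on the background — the synthetic analogue of a quantitative
#' phase resolution target used to measure phase accuracy as the bar/background
#' phase difference.
#'
#' @param side image side in pixels.
#' @param delta_phi phase step in radians, `|delta_phi| <= pi` (a larger step
#'   would alias after wrapping).
#' @param bar_width_px bar width in pixels.
#' @return a [complex_image()].
#' @export
phase_step_target <- function(side, delta_phi, bar_width_px = max(1L, side %/% 16L)) {
  if (abs(delta_phi) > pi) {
    rlang::abort("|delta_phi| must not exceed pi (it would alias after wrapping).",
      class = "holopix_invalid")
  }
  w <- as.integer(bar_width_px)
  corner <- as.integer((side - 5L * w) %/% 2L) + 1L
  mask <- three_bar_mask(side, w, "vertical", row0 = corner, col0 = corner)
  ph <- matrix(0, side, side)
  ph[mask] <- delta_phi
  complex_image(matrix(1, side, side), ph)
}

# periodic Gaussian smoothing via FFT
smooth_field <- function(x, corr_len) {
  side <- nrow(x)
  d <- 0:(side - 1)
  d <- pmin(d, side - d)
  g <- exp(-0.5 * (d / corr_len)^2)
  K <- outer(g, g)
  Re(stats::fft(stats::fft(x) * stats::fft(K / sum(K)), inverse = TRUE)) / side^2
}

#' Tissue-like random phantom
#'
#' A seeded, smoothed Gaussian random field standing in for a thin tissue
#' slice: amplitude mapped into `[1 - amp_contrast, 1]` and phase into
#' `[-phase_range / 2, phase_range / 2]`. Low `amp_contrast` with a rich
#' `phase_range` emulates unstained tissue (low transmission contrast, strong
#' phase contrast); a higher `amp_contrast` emulates stained sections.
#' Deterministic for a fixed seed.
#'
#' @param side image side in pixels.
#' @param seed integer RNG seed.
#' @param amp_contrast peak-to-peak amplitude variation in `[0, 1]`.
#' @param phase_range peak-to-peak phase variation in radians (`<= 2 pi`).
#' @param correlation_len_px smoothing length of the field in pixels
#'   (feature size).
#' @return a [complex_image()].
#' @export
tissue_phantom <- function(side, seed, amp_contrast = 0.3, phase_range = pi,
                           correlation_len_px = 8) {
  if (correlation_len_px < 1) {
    rlang::abort("`correlation_len_px` must be >= 1.", class = "holopix_invalid")
  }
  fields <- withr::with_seed(as.integer(seed), {
    list(a = matrix(stats::rnorm(side^2), side, side),
         p = matrix(stats::rnorm(side^2), side, side))
  })
  rescale01 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(x * 0 + 0.5)
    (x - rng[1]) / diff(rng)
  }
  a <- rescale01(smooth_field(fields$a, correlation_len_px))
  p <- rescale01(smooth_field(fields$p, correlation_len_px))
  complex_image(
    1 - amp_contrast + amp_contrast * a,
    phase_range * (p - 0.5)
  )
}
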