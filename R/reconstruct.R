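# From measured binary-pattern coefficients to images: DC correction into the
# orthogonal basis, zero-filled inverse fast transform, and the end-to-end
# pipeline.

#' Compressive sampling plan
#'
#' Keeps the first `ceiling(sr * N)` orders of the square sampling path —
#' the lowest spatial frequencies. `sr` is the sampling ratio: measurements
#' used for reconstruction divided by pixels in the reconstructed image.
#'
#' @param plan a [hadamard_plan()].
#' @param sr sampling ratio in `(0, 1]`; the reference choices are
#'   1, 0.5, 0.25, 0.125, 0.0625 and 0.03125.
#' @return a `sampling_plan` list with `sr` and `orders` (a path prefix,
#'   always containing order 1).
#' @export
sampling_plan <- function(plan, sr = 1) {
  if (length(sr) != 1 || is.na(sr) || sr <= 0 || sr > 1) {
    rlang::abort("`sr` must lie in (0, 1].", class = "holopix_invalid")
  }
  n_keep <- max(1L, as.integer(ceiling(sr * plan$n_total)))
  structure(list(sr = sr, orders = plan$path[seq_len(n_keep)]),
            class = "sampling_plan")
}

#' Correct binary-pattern coefficients to the orthogonal basis
#'
#' The binary (0/1) patterns are not orthogonal; the all-ones (DC)
#' measurement fixes that with one linear identity per order:
#' `a_n = 2 a~_n - a~_1` (at `n = 1` this reduces to `a_1 = a~_1`). This is
#' the step that lets a binary-amplitude modulator do holography without
#' phase-encoded patterns.
#'
#' @param coeffs an `sph_coeffs` tibble of kind `"binary"` containing
#'   order 1.
#' @return an `sph_coeffs` tibble of kind `"bipolar"`.
#' @export
dc_correct <- function(coeffs) {
  if (!any(coeffs$order == 1L)) {
    rlang::abort("order 1 (the DC coefficient) is required for the correction.",
      class = "holopix_invalid")
  }
  a1 <- coeffs$value[coeffs$order == 1L][[1L]]
  out <- coeffs
  out$value <- 2 * coeffs$value - a1
  out$value[coeffs$order == 1L] <- a1
  attr(out, "kind") <- "bipolar"
  out
}

#' Reconstruct the complex image from corrected coefficients
#'
#' Zero-fills every unmeasured order and applies the inverse fast transform
#' (the same basis used for measurement). The output amplitude is the
#' modulus and the phase the argument wrapped to `(-pi, pi]` — phase is
#' never unwrapped.
#'
#' @param coeffs an `sph_coeffs` tibble of kind `"bipolar"`.
#' @param plan the matching [hadamard_plan()].
#' @param sampling optional [sampling_plan()]; when given, only its orders
#'   are used even if more coefficients are present.
#' @return a [complex_image()] (amplitude not clamped to `[0, 1]`: noise can
#'   push the modulus slightly above the physical range).
#' @export
reconstruct_image <- function(coeffs, plan, sampling = NULL) {
  if (!is.null(sampling)) {
    coeffs <- coeffs[coeffs$order %in% sampling$orders, ]
  }
  z <- ifwht2(coeffs, plan)
  complex_image_from_matrix(z, check_amplitude = FALSE)
}

#' End-to-end simulated acquisition and reconstruction
#'
#' Runs the whole measurement chain on a synthetic object:
#' acquire (beat records) -> demodulate (measured coefficients) ->
#' DC-correct (orthogonal basis) -> inverse transform (complex image).
#' Deterministic for a fixed seed.
#'
#' @param object a [complex_image()].
#' @param sr sampling ratio in `(0, 1]`.
#' @param config an [acquisition_config()].
#' @param seed RNG seed for the measurement noise.
#' @param plan optional [hadamard_plan()] (defaults to the object's side).
#' @param method forwarded to [acquire()].
#' @return an `sph_recon`: list with `image` ([complex_image()]),
#'   `coeffs_measured`, `coeffs_corrected`, `truth` (the input object) and a
#'   `meta` list (side, sr, record/sample counts, simulated duration,
#'   elapsed wall time).
#' @export
run_pipeline <- function(object, sr = 1, config = acquisition_config(),
                         seed = config$seed, plan = NULL,
                         method = c("fht", "direct")) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(plan)) plan <- hadamard_plan(object$side)
  sampling <- sampling_plan(plan, sr)
  beats <- acquire(object, plan, sampling, config, seed = seed,
                   method = match.arg(method))
  measured <- batch_demodulate(beats, config)
  corrected <- dc_correct(measured)
  image <- reconstruct_image(corrected, plan, sampling)
  structure(
    list(
      image = image,
      coeffs_measured = measured,
      coeffs_corrected = corrected,
      truth = object,
      meta = list(
        side = plan$side, sr = sr,
        n_records = nrow(beats$samples),
        samples_per_record = ncol(beats$samples),
        total_time = nrow(beats$samples) * config$refresh_time,
        elapsed = proc.time()[["elapsed"]] - t0
      )
    ),
    class = "sph_recon"
  )
}

#' @export
print.sph_recon <- function(x, ...) {
  cat(sprintf(
    "<sph_recon> side %d, SR %.4g%%: %d records x %d samples (simulated %.4g s, computed in %.2f s)\n",
    x$meta$side, 100 * x$meta$sr, x$meta$n_records, x$meta$samples_per_record,
    x$meta$total_time, x$meta$elapsed))
  invisible(x)
}

#' Tidy the reconstruction's coefficients
#'
#' @param x an `sph_recon`.
#' @param ... unused.
#' @return tibble with `order`, `u`, `v`, `measured`, `corrected` (complex).
#' @method tidy sph_recon
#' @export
tidy.sph_recon <- function(x, ...) {
  dplyr::mutate(
    tibble::as_tibble(x$coeffs_measured[, c("order", "u", "v")]),
    measured = x$coeffs_measured$value,
    corrected = x$coeffs_corrected$value
  )
}

#' One-row summary of a reconstruction
#'
#' Reports the run's size plus fidelity against the true object: the
#' maximum modulus error `max |O_rec - O|` and the global-phase-invariant
#' complex correlation.
#'
#' @param x an `sph_recon`.
#' @param ... unused.
#' @return a one-row tibble.
#' @method glance sph_recon
#' @export
glance.sph_recon <- function(x, ...) {
  zr <- as_complex_matrix(x$image)
  zt <- as_complex_matrix(x$truth)
  tibble::tibble(
    side = x$meta$side, sr = x$meta$sr, n_records = x$meta$n_records,
    total_time = x$meta$total_time,
    max_modulus_error = max(Mod(zr - zt)),
    complex_correlation = complex_correlation(x$image, x$truth),
    elapsed = x$meta$elapsed
  )
}

#' Plot a reconstructed component
#'
#' @param object an `sph_recon`.
#' @param component `"amplitude"` or `"phase"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sph_recon
#' @export
autoplot.sph_recon <- function(object, component = c("amplitude", "phase"), ...) {
  autoplot.complex_image(object$image, component = component) +
    ggplot2::ggtitle(sprintf("SR = %.4g%%", 100 * object$meta$sr))
}
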