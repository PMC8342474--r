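# Quadrature demodulation: the phase stepping happens naturally in time, so
# each record is a single known-frequency tone whose amplitude and absolute
# phase carry the complex measurement coefficient.

design_matrix <- function(t, beat_freq) {
  w <- 2 * pi * beat_freq * t
  cbind(1, cos(w), sin(w))
}

solve_tone <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank < 3L) {
    rlang::abort("degenerate single-tone fit (is beat_freq zero, or the record too short?).",
      class = "holopix_degenerate")
  }
  qr.coef(qr_x, y)
}

coef_from_quadrature <- function(beta, gain) {
  (beta[2L, ] - 1i * beta[3L, ]) / (2 * gain)
}

#' Demodulate one beat record
#'
#' Least-squares fit of the samples to
#' `c0 + cc * cos(2 pi beat_freq t) + cs * sin(2 pi beat_freq t)` using
#' absolute times `t = t_start + j / sample_rate`, then
#' `coeff = (cc - i cs) / (2 gain)`, so that `Mod(coeff)` is the measured
#' amplitude and `Arg(coeff)` the absolute phase referenced to the global
#' clock. The intercept absorbs all DC, so any constant offset is rejected
#' exactly; the fit is exact (to solver precision) for a noise-free record
#' holding an integer number of beat cycles. This is the one place the
#' `exp(+i w t)` sign convention is fixed: [synthesize_beat()] followed by
#' `demodulate()` is the identity.
#'
#' @param record an `sph_beat` from [synthesize_beat()], or a numeric vector
#'   of samples (then `t_start` applies).
#' @param config the [acquisition_config()] used for the record.
#' @param t_start start time when `record` is a bare numeric vector.
#' @return a single complex coefficient.
#' @export
demodulate <- function(record, config, t_start = 0) {
  if (inherits(record, "sph_beat")) {
    samples <- record$samples
    t_start <- record$t_start
  } else {
    samples <- as.numeric(record)
  }
  if (length(samples) < 3L) {
    rlang::abort("at least 3 samples are required for the three-parameter fit.",
      class = "holopix_invalid")
  }
  t <- t_start + (0:(length(samples) - 1L)) / config$sample_rate
  beta <- solve_tone(design_matrix(t, config$beat_freq), samples)
  coef_from_quadrature(matrix(beta, 3L, 1L), config$gain)[[1L]]
}

#' Demodulate a full acquisition
#'
#' One coefficient per record. When the configuration locks an integer
#' number of beat cycles per pattern, every record sees the identical time
#' grid modulo the beat period, so a single shared least-squares solve
#' (one pseudoinverse applied to all rows) is used; otherwise each record is
#' fit with its absolute times.
#'
#' @param beats an `sph_beats` bundle from [acquire()].
#' @param config an [acquisition_config()]; defaults to the one stored in
#'   `beats`.
#' @return an `sph_coeffs` tibble of kind `"binary"` (the measured
#'   `a~_n exp(i phi~_n)`).
#' @export
batch_demodulate <- function(beats, config = beats$config) {
  if (!inherits(beats, "sph_beats") || nrow(beats$samples) == 0L) {
    rlang::abort("`beats` must be a non-empty sph_beats bundle.",
      class = "holopix_invalid")
  }
  if (!any(beats$meta$order == 1L)) {
    rlang::abort("order 1 (the DC record) is missing from the acquisition.",
      class = "holopix_invalid")
  }
  m <- ncol(beats$samples)
  if (integer_cycles(config)) {
    tau <- (0:(m - 1L)) / config$sample_rate
    X <- design_matrix(tau, config$beat_freq)
    beta <- solve_tone(X, t(beats$samples))
    values <- coef_from_quadrature(beta, config$gain)
  } else {
    values <- vapply(seq_len(nrow(beats$samples)), function(k) {
      t <- beats$meta$t_start[k] + (0:(m - 1L)) / config$sample_rate
      beta <- solve_tone(design_matrix(t, config$beat_freq), beats$samples[k, ])
      coef_from_quadrature(matrix(beta, 3L, 1L), config$gain)[[1L]]
    }, complex(1))
  }
  side <- if (is.null(beats$side)) NA_integer_ else beats$side
  coeffs_tibble(beats$meta$order, beats$meta$u, beats$meta$v, values,
                kind = "binary", side = side)
}
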