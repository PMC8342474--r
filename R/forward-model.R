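# Heterodyne single-pixel forward model: project a binary pattern onto the
# object, take the spatial sum of the transmitted field, and synthesise the
# digitised beat signal the photodetector + acquisition card record.

#' Acquisition configuration
#'
#' Timing and noise constants of the heterodyne measurement. The defaults
#' are the reference system: beat frequency 62,500 Hz between the two
#' frequency-shifted arms (16 us period), 1.25 Ms/s digitiser, 48 us pattern
#' refresh time — three beat cycles and 60 samples per displayed pattern —
#' and measurement noise with standard deviation 0.1% of the measured value.
#'
#' @param beat_freq beat (difference) frequency in Hz.
#' @param sample_rate digitiser rate in samples/s; must satisfy Nyquist
#'   (`beat_freq <= sample_rate / 2`).
#' @param refresh_time seconds each pattern is displayed. A non-integer
#'   number of beat cycles per pattern is allowed but triggers a warning:
#'   integer cycle locking is the computationally convenient choice.
#' @param noise_rel relative noise standard deviation (0.001 = 0.1% of the
#'   noiseless sample value).
#' @param dc_reference detector DC offset contributed by the reference arm
#'   intensity (arbitrary units).
#' @param gain interference scaling constant (arbitrary units; cancels in
#'   reconstruction up to a global factor).
#' @param seed default RNG seed for the noise stream.
#' @return an `acq_config` list.
#' @export
acquisition_config <- function(beat_freq = 62500, sample_rate = 1.25e6,
                               refresh_time = 48e-6, noise_rel = 0.001,
                               dc_reference = 1, gain = 1, seed = 1L) {
  if (beat_freq <= 0 || sample_rate <= 0 || refresh_time <= 0) {
    rlang::abort("beat_freq, sample_rate and refresh_time must be positive.",
      class = "holopix_invalid")
  }
  if (beat_freq > sample_rate / 2) {
    rlang::abort("Nyquist violated: beat_freq must be <= sample_rate / 2.",
      class = "holopix_invalid")
  }
  if (noise_rel < 0) {
    rlang::abort("`noise_rel` must be non-negative.", class = "holopix_invalid")
  }
  cycles <- refresh_time * beat_freq
  if (abs(cycles - round(cycles)) > 1e-9) {
    rlang::warn(sprintf(
      "refresh_time * beat_freq = %.4g is not an integer; an integer number of beat cycles per pattern is preferred.",
      cycles))
  }
  structure(
    list(beat_freq = beat_freq, sample_rate = sample_rate,
         refresh_time = refresh_time, noise_rel = noise_rel,
         dc_reference = dc_reference, gain = gain, seed = as.integer(seed)),
    class = "acq_config"
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat(sprintf(
    "<acq_config> beat %g Hz, %g samples/s, refresh %g us (%.3g cycles, %d samples/pattern), noise %.3g%%\n",
    x$beat_freq, x$sample_rate, x$refresh_time * 1e6,
    x$refresh_time * x$beat_freq, samples_per_pattern(x), 100 * x$noise_rel))
  invisible(x)
}

samples_per_pattern <- function(config) {
  as.integer(floor(config$refresh_time * config$sample_rate + 1e-9))
}

integer_cycles <- function(config) {
  cyc <- config$refresh_time * config$beat_freq
  abs(cyc - round(cyc)) < 1e-9
}

#' Project a pattern and sum the transmitted field
#'
#' The single-pixel measurement kernel: the spatial sum of the field
#' transmitted through the illuminated pixels, `(1 / sqrt(N)) * sum_r O(r)
#' P(r)`. With the binary (0/1) pattern this is the measured coefficient
#' `a~_n exp(i phi~_n)`; with the bipolar pattern it is the orthogonal-basis
#' coefficient `a_n exp(i phi_n)` (useful as an oracle).
#'
#' @param object a [complex_image()] or complex matrix.
#' @param pattern an `sph_pattern` from [basis_pattern()].
#' @return a single complex coefficient.
#' @export
project_and_sum <- function(object, pattern) {
  O <- as_complex_matrix(object)
  if (!all(dim(O) == dim(pattern$values))) {
    rlang::abort("object and pattern sides differ.", class = "holopix_invalid")
  }
  sum(O * pattern$values) / sqrt(length(O))
}

#' Synthesise one digitised beat record
#'
#' The detector voltage while pattern `n` is displayed oscillates at the
#' beat frequency with the coefficient's modulus as amplitude and its
#' argument as phase:
#' `V(t) = dc_reference + dc_signal + 2 * gain * |c| * cos(2 pi beat_freq t + arg c) + eps`,
#' sampled at `t = t_start + j / sample_rate`. The carrier phase is
#' referenced to the global clock `t = 0`, so the absolute phase is encoded.
#' `eps` is zero-mean Gaussian with standard deviation `noise_rel` times the
#' noiseless sample (drawn from the current RNG stream).
#'
#' @param coeff complex coefficient `a~_n exp(i phi~_n)`.
#' @param config an [acquisition_config()].
#' @param order pattern order (bookkeeping only).
#' @param t_start record start time on the global clock, seconds.
#' @param dc_signal pattern-dependent transmitted-intensity DC term.
#' @return an `sph_beat`: list with `order`, `t_start`, `samples`.
#' @export
synthesize_beat <- function(coeff, config, order = 1L, t_start = 0,
                            dc_signal = 0) {
  if (length(coeff) != 1 || !is.finite(Re(coeff)) || !is.finite(Im(coeff))) {
    rlang::abort("`coeff` must be a single finite complex number.",
      class = "holopix_invalid")
  }
  m <- samples_per_pattern(config)
  t <- t_start + (0:(m - 1L)) / config$sample_rate
  v <- config$dc_reference + dc_signal +
    2 * config$gain * Mod(coeff) * cos(2 * pi * config$beat_freq * t + Arg(coeff))
  if (config$noise_rel > 0) {
    v <- v + abs(v) * config$noise_rel * stats::rnorm(m)
  }
  structure(list(order = as.integer(order), t_start = t_start, samples = v),
            class = "sph_beat")
}

#' Simulate a full acquisition
#'
#' Displays the sampled patterns in path order on one continuous global
#' clock (`t_start = (k - 1) * refresh_time`) and records each beat signal.
#' The `"fht"` method computes all binary-pattern coefficients at once from
#' the fast transform via `a~_n = (a_n + a_1) / 2` (and the per-pattern
#' transmitted-intensity DC the same way from `|O|^2`); `"direct"` projects
#' every pattern explicitly and is the slow oracle the fast path is tested
#' against.
#'
#' @param object a [complex_image()].
#' @param plan a [hadamard_plan()] of matching side.
#' @param sampling a [sampling_plan()]; defaults to full sampling. Must
#'   contain order 1 (the DC record every reconstruction needs).
#' @param config an [acquisition_config()].
#' @param seed RNG seed for the noise stream (defaults to `config$seed`).
#' @param method `"fht"` (fast) or `"direct"` (per-pattern projection).
#' @return an `sph_beats` bundle: `meta` tibble (`order`, `u`, `v`,
#'   `t_start`), `samples` matrix (one row per record), and `config`.
#' @export
acquire <- function(object, plan, sampling = NULL, config = acquisition_config(),
                    seed = config$seed, method = c("fht", "direct")) {
  method <- match.arg(method)
  if (is.null(sampling)) sampling <- sampling_plan(plan, 1)
  orders <- sampling$orders
  if (!any(orders == 1L)) {
    rlang::abort("the sampling plan must include order 1 (the DC pattern).",
      class = "holopix_invalid")
  }
  if (any(orders < 1 | orders > plan$n_total)) {
    rlang::abort("sampling plan contains orders outside the plan.",
      class = "holopix_invalid")
  }
  O <- as_complex_matrix(object)
  if (!all(dim(O) == plan$side)) {
    rlang::abort("object side does not match the plan.", class = "holopix_invalid")
  }

  if (method == "fht") {
    a <- fwht2(O, plan)$value
    p <- Re(fwht2(Mod(O)^2 + 0i, plan)$value)
    coeff <- (a[orders] + a[1L]) / 2
    dc_sig <- (p[orders] + p[1L]) / 2
  } else {
    coeff <- vapply(orders, function(n) {
      project_and_sum(O, basis_pattern(plan, n, "binary"))
    }, complex(1))
    I <- Mod(O)^2
    dc_sig <- purrr::map_dbl(orders, function(n) {
      Re(sum(I * basis_pattern(plan, n, "binary")$values)) / sqrt(length(I))
    })
  }

  m <- samples_per_pattern(config)
  k <- seq_along(orders)
  t_start <- (k - 1) * config$refresh_time
  tau <- (0:(m - 1L)) / config$sample_rate
  ph <- outer(2 * pi * config$beat_freq * t_start + Arg(coeff),
              2 * pi * config$beat_freq * tau, "+")
  V <- config$dc_reference + dc_sig + (2 * config$gain * Mod(coeff)) * cos(ph)
  if (config$noise_rel > 0) {
    noise <- withr::with_seed(as.integer(seed),
      matrix(stats::rnorm(length(V)), nrow(V), ncol(V)))
    V <- V + abs(V) * config$noise_rel * noise
  }

  structure(
    list(
      meta = tibble::tibble(order = as.integer(orders),
                            u = plan$uv[orders, 1], v = plan$uv[orders, 2],
                            t_start = t_start),
      samples = V,
      config = config,
      side = plan$side
    ),
    class = "sph_beats"
  )
}

#' @export
print.sph_beats <- function(x, ...) {
  cat(sprintf("<sph_beats> %d records x %d samples (%.4g s total)\n",
              nrow(x$samples), ncol(x$samples),
              nrow(x$samples) * x$config$refresh_time))
  invisible(x)
}

#' Tidy beat records into a long tibble
#'
#' @param x an `sph_beats` bundle.
#' @param ... unused.
#' @return tibble with `order`, `t`, `value`, one row per sample.
#' @method tidy sph_beats
#' @export
tidy.sph_beats <- function(x, ...) {
  m <- ncol(x$samples)
  tau <- (0:(m - 1L)) / x$config$sample_rate
  tibble::tibble(
    order = rep(x$meta$order, each = m),
    t = rep(x$meta$t_start, each = m) + rep(tau, times = nrow(x$samples)),
    value = as.vector(t(x$samples))
  )
}
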