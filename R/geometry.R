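# Optical and temporal system calculators: lateral resolution, field of view
# and throughput (SBP-T) for the operational modes, and the beat/sampling
# timing budget per displayed pattern.

#' Optical system configuration
#'
#' Hardware constants of the projection chain: the micromirror pitch, the
#' binning of mirrors into superpixels, the 4f relay magnification
#' (`f_rear / f_front`), and two geometric constants from the 45-degree
#' diagonal mounting of the mirror device — the `sqrt(2)` diagonal factor on
#' the x pitch and the y/x resolution anisotropy (default `43.1 / 58.0`,
#' matching the printed resolution pair; numerically close to the cosine of
#' the diffraction angle).
#'
#' @param mirror_pitch micromirror pitch in micrometres.
#' @param binning mirrors per superpixel edge (3 or 2 in the reference
#'   modes).
#' @param n_super superpixels per edge of the displayed pattern.
#' @param f_front,f_rear 4f focal lengths in mm; magnification is
#'   `f_rear / f_front`.
#' @param diag_factor diagonal mounting factor (default `sqrt(2)`).
#' @param anisotropy y-to-x resolution ratio.
#' @return a `system_config` list.
#' @export
system_config <- function(mirror_pitch = 13.68, binning = 3L, n_super = 256L,
                          f_front = 125, f_rear = 125,
                          diag_factor = sqrt(2), anisotropy = 43.1 / 58.0) {
  if (mirror_pitch <= 0 || f_front <= 0 || f_rear <= 0 || diag_factor <= 0) {
    rlang::abort("all lengths and factors must be positive.",
      class = "holopix_invalid")
  }
  if (binning * n_super > 768) {
    rlang::abort("binning * n_super exceeds the 768-mirror short edge.",
      class = "holopix_invalid")
  }
  structure(
    list(mirror_pitch = mirror_pitch, binning = as.integer(binning),
         n_super = as.integer(n_super), f_front = f_front, f_rear = f_rear,
         diag_factor = diag_factor, anisotropy = anisotropy),
    class = "system_config"
  )
}

#' Derived optical geometry of an operational mode
#'
#' Lateral resolution is the superpixel footprint at the sample plane,
#' `res_x = diag_factor * binning * mirror_pitch * (f_rear / f_front)` and
#' `res_y = anisotropy * res_x`; the field of view is `n_super` resolution
#' elements per axis; the throughput is `sbp_t = 2 / refresh_time`
#' (amplitude and phase both count, hence the factor 2), independent of the
#' lens pair and binning.
#'
#' @param sys a [system_config()].
#' @param acq an [acquisition_config()] (supplies the refresh time).
#' @return a one-row tibble: `res_x`, `res_y` (um), `fov_x`, `fov_y` (mm),
#'   `sbp_t` (pixels/s). Values are full precision; round only for display.
#' @export
derive_geometry <- function(sys, acq = acquisition_config()) {
  stopifnot(inherits(sys, "system_config"))
  res_x <- sys$diag_factor * sys$binning * sys$mirror_pitch *
    (sys$f_rear / sys$f_front)
  res_y <- sys$anisotropy * res_x
  tibble::tibble(
    res_x = res_x, res_y = res_y,
    fov_x = sys$n_super * res_x / 1000,
    fov_y = sys$n_super * res_y / 1000,
    sbp_t = 2 / acq$refresh_time
  )
}

#' Timing budget of the acquisition
#'
#' How the beat cycles and digitiser samples tile one displayed pattern,
#' and the total acquisition time for `n_patterns` patterns. With the
#' defaults: 3 beat cycles and 60 samples per pattern, 20 samples per cycle,
#' a 16 us beat period, and 3.15 s for a full 256 x 256 acquisition.
#'
#' @param acq an [acquisition_config()].
#' @param n_patterns number of patterns displayed.
#' @return a one-row tibble: `cycles_per_pattern`, `samples_per_cycle`,
#'   `samples_per_pattern`, `beat_period` (s), `total_time` (s).
#' @export
timing_report <- function(acq, n_patterns = 65536L) {
  stopifnot(inherits(acq, "acq_config"))
  tibble::tibble(
    cycles_per_pattern = acq$refresh_time * acq$beat_freq,
    samples_per_cycle = acq$sample_rate / acq$beat_freq,
    samples_per_pattern = acq$sample_rate * acq$refresh_time,
    beat_period = 1 / acq$beat_freq,
    total_time = n_patterns * acq$refresh_time
  )
}
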