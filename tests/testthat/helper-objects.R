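# shared fixture builders; all randomness is seeded locally

random_complex_image <- function(side, seed = 1) {
  withr::with_seed(seed, {
    amp <- matrix(stats::runif(side^2, 0.05, 1), side, side)
    ph <- matrix(stats::runif(side^2, -pi + 1e-6, pi), side, side)
    complex_image(amp, ph)
  })
}

noise_free_config <- function(...) {
  acquisition_config(noise_rel = 0, ...)
}

count_sign_changes <- function(row) {
  sum(diff(sign(row)) != 0)
}
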