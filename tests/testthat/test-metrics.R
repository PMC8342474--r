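test_that("line profiles resolve the three bars of a reconstructed target", {
  obj <- bar_target(64, bar_width_px = 4, orientation_mix = "vertical")
  rec <- run_pipeline(obj, sr = 1, config = noise_free_config())
  # across the bars (vertical bars -> horizontal profile): 3 plateaus at 1
  prof <- line_profile(rec$image, c(18, 8), c(18, 27), width_px = 3)
  runs <- rle(round(prof$value, 6))
  expect_equal(runs$values, c(1, 0, 1, 0, 1))
  expect_equal(runs$lengths, rep(4, 5))
  # uniform image: constant profile; width 1 equals direct sampling
  uni <- complex_image(matrix(0.5, 16, 16))
  expect_true(all(line_profile(uni, c(3, 1), c(3, 16))$value == 0.5))
  m <- matrix(seq_len(64) / 64, 8, 8)
  expect_equal(line_profile(m, c(2, 1), c(2, 8), width_px = 1)$value, m[2, ])
  expect_error(line_profile(m, c(0, 1), c(2, 8)), class = "holopix_invalid")
})

test_that("phase error reproduces the reference bar/background arithmetic", {
  # a two-level phase field measured at 1.691 rad against a nominal step of
  # 1.795 rad must report an error of 0.104 rad
  ph <- matrix(0, 8, 8)
  ph[3:6, 3:6] <- 1.691
  img <- complex_image(matrix(1, 8, 8), ph)
  res <- phase_error(img, roi_bar = list(rows = 3:6, cols = 3:6),
                     roi_bg = list(rows = 1:2, cols = 1:8), nominal = 1.795)
  expect_equal(res$measured_step, 1.691)
  expect_equal(res$error, 0.104)
  # nominal equal to measured: zero error
  res0 <- phase_error(img, list(rows = 3:6, cols = 3:6),
                      list(rows = 1:2, cols = 1:8), nominal = 1.691)
  expect_equal(res0$error, 0)
  expect_error(phase_error(img, list(rows = 3:6, cols = 3:6),
                           list(rows = 9:10, cols = 1:2), 1),
               class = "holopix_invalid")
})

test_that("a noise-free reconstruction of the phase target is phase-accurate", {
  dphi <- 1.795
  obj <- phase_step_target(64, dphi, bar_width_px = 4)
  rec <- run_pipeline(obj, sr = 1, config = noise_free_config())
  bars <- obj$phase != 0
  res <- phase_error(rec$image, bars, !bars, nominal = dphi)
  expect_lt(res$error, 1e-8)
})

test_that("phase error is invariant to a global phase offset", {
  obj <- phase_step_target(32, 1.2, bar_width_px = 2)
  z <- as_complex_matrix(obj) * exp(1i * 2.9) # pushes phases across the wrap
  shifted <- complex_image_from_matrix(z)
  bars <- obj$phase != 0
  res <- phase_error(shifted, bars, !bars, nominal = 1.2)
  expect_equal(res$error, 0, tolerance = 1e-12)
})

test_that("contrast-to-noise ratio follows its definition and noise ordering", {
  img <- matrix(0, 16, 16)
  img[1:4, 1:4] <- 1
  img[9:16, 9:16] <- withr::with_seed(1, stats::rnorm(64, mean = 0, sd = 0.1))
  sig <- list(rows = 1:4, cols = 1:4)
  bg <- list(rows = 9:16, cols = 9:16)
  bgv <- as.vector(img[9:16, 9:16])
  expect_equal(cnr(img, sig, bg), (1 - mean(bgv)) / sd(bgv))
  # noiseless background: undefined
  expect_error(cnr(matrix(c(rep(1, 8), rep(0, 8)), 4, 4),
                   list(rows = 1:2, cols = 1:2), list(rows = 3:4, cols = 3:4)),
               class = "holopix_undefined_metric")
  # more noise, lower expected CNR (Monte-Carlo over 20 seeds)
  mean_cnr <- function(noise_sd) {
    mean(vapply(1:20, function(s) {
      m <- matrix(0, 16, 16)
      m[1:4, 1:4] <- 1
      m <- m + withr::with_seed(s, matrix(stats::rnorm(256, sd = noise_sd), 16, 16))
      cnr(m, sig, bg)
    }, numeric(1)))
  }
  expect_gt(mean_cnr(0.05), mean_cnr(0.2))
})

test_that("complex correlation is 1 up to global phase and 0 for disjoint supports", {
  a <- random_complex_image(16, seed = 2)
  expect_equal(complex_correlation(a, a), 1)
  za <- as_complex_matrix(a)
  expect_equal(complex_correlation(complex_image_from_matrix(za * exp(1i * 1.3)), a), 1)
  m1 <- matrix(0 + 0i, 8, 8); m1[1:4, ] <- 1
  m2 <- matrix(0 + 0i, 8, 8); m2[5:8, ] <- 1
  expect_equal(complex_correlation(m1, m2), 0)
  expect_error(complex_correlation(m1, matrix(0 + 0i, 8, 8)),
               class = "holopix_undefined_metric")
})
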