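test_that("sampling plans are path prefixes containing the DC order", {
  plan <- hadamard_plan(16)
  for (sr in c(0.03125, 0.125, 1)) {
    sp <- sampling_plan(plan, sr)
    expect_equal(sp$orders, plan$path[seq_len(ceiling(sr * plan$n_total))])
    expect_true(1L %in% sp$orders)
  }
  expect_error(sampling_plan(plan, 0), class = "holopix_invalid")
  expect_error(sampling_plan(plan, 1.2), class = "holopix_invalid")
})

test_that("DC correction maps binary measurements onto the orthogonal basis", {
  plan <- hadamard_plan(8)
  cfg <- noise_free_config()
  # uniform object: every non-DC binary coefficient is half the DC one,
  # so the corrected spectrum is DC-only
  uni <- complex_image(matrix(0.8, 8, 8))
  cu <- dc_correct(batch_demodulate(acquire(uni, plan, config = cfg)))
  expect_equal(cu$value[1], 8 * 0.8 + 0i, tolerance = 1e-9)
  expect_lt(max(Mod(cu$value[-1])), 1e-9)
  # a lone DC coefficient passes through unchanged
  lone <- dc_correct(coeffs_tibble(1L, 0L, 0L, 3 + 2i, "binary", 8L))
  expect_equal(lone$value, 3 + 2i)
  # random object: corrected measurement equals direct bipolar projection
  obj <- random_complex_image(8, seed = 17)
  corr <- dc_correct(batch_demodulate(acquire(obj, plan, config = cfg,
                                              method = "direct")))
  oracle <- vapply(seq_len(plan$n_total), function(n) {
    project_and_sum(obj, basis_pattern(plan, n, "bipolar"))
  }, complex(1))
  expect_lt(max(Mod(corr$value - oracle)), 1e-10)
  no_dc <- corr[corr$order > 1, ]
  expect_error(dc_correct(no_dc), class = "holopix_invalid")
})

test_that("full sampling without noise reconstructs the object exactly", {
  for (s in c(16, 64)) {
    obj <- random_complex_image(s, seed = s + 1)
    rec <- run_pipeline(obj, sr = 1, config = noise_free_config())
    err <- max(Mod(as_complex_matrix(rec$image) - as_complex_matrix(obj)))
    expect_lt(err, 1e-8)
    expect_gt(complex_correlation(rec$image, obj), 1 - 1e-12)
  }
})

test_that("a uniform object is recovered exactly at any sampling ratio", {
  obj <- complex_image(matrix(0.6, 16, 16), matrix(0.4, 16, 16))
  rec <- run_pipeline(obj, sr = 0.03125, config = noise_free_config())
  expect_lt(max(Mod(as_complex_matrix(rec$image) - as_complex_matrix(obj))),
            1e-9)
})

test_that("reconstruction error is non-increasing in the sampling ratio", {
  obj <- tissue_phantom(32, seed = 23, amp_contrast = 0.4, phase_range = 2)
  srs <- c(0.03125, 0.0625, 0.125, 0.25, 0.5, 1)
  l2 <- vapply(srs, function(sr) {
    rec <- run_pipeline(obj, sr = sr, config = noise_free_config())
    sqrt(sum(Mod(as_complex_matrix(rec$image) - as_complex_matrix(obj))^2))
  }, numeric(1))
  expect_true(all(diff(l2) <= 1e-9))
  # and the truncation identity: L2 error^2 = energy of the dropped orders
  plan <- hadamard_plan(32)
  cf <- fwht2(obj, plan)
  sp <- sampling_plan(plan, 0.25)
  rec <- run_pipeline(obj, sr = 0.25, config = noise_free_config())
  expect_equal(
    sum(Mod(as_complex_matrix(rec$image) - as_complex_matrix(obj))^2),
    sum(Mod(cf$value[-sp$orders])^2),
    tolerance = 1e-6
  )
})

test_that("the pipeline is linear in the object and seed-deterministic", {
  obj <- random_complex_image(16, seed = 3)
  half <- complex_image(obj$amplitude / 2, obj$phase)
  cfg <- noise_free_config()
  r1 <- run_pipeline(obj, sr = 0.25, config = cfg)
  r2 <- run_pipeline(half, sr = 0.25, config = cfg)
  expect_equal(as_complex_matrix(r2$image), as_complex_matrix(r1$image) / 2,
               tolerance = 1e-9)
  cfgn <- acquisition_config(noise_rel = 0.001)
  a <- run_pipeline(obj, sr = 0.5, config = cfgn, seed = 12)
  b <- run_pipeline(obj, sr = 0.5, config = cfgn, seed = 12)
  expect_identical(a$image, b$image)
})

test_that("reconstructed phase stays wrapped in (-pi, pi]", {
  obj <- tissue_phantom(16, seed = 6, phase_range = 2 * pi - 1e-6)
  rec <- run_pipeline(obj, sr = 0.5, config = acquisition_config(seed = 2))
  expect_gt(min(rec$image$phase), -pi)
  expect_lte(max(rec$image$phase), pi)
})

test_that("tidy and glance expose the run's coefficients and fidelity", {
  obj <- random_complex_image(16, seed = 8)
  rec <- run_pipeline(obj, sr = 0.5, config = noise_free_config())
  td <- tidy(rec)
  expect_named(td, c("order", "u", "v", "measured", "corrected"))
  expect_equal(nrow(td), ceiling(0.5 * 256))
  gl <- glance(rec)
  expect_equal(gl$n_records, nrow(td))
  expect_lt(gl$max_modulus_error, 1) # truncation only
  p <- autoplot(rec, "phase")
  expect_s3_class(p, "ggplot")
})
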