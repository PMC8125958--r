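test_that("default cohort has the full sampling design", {
  co <- generate_cohort(cohort_config(seed = 3))
  expect_equal(nrow(co), 160L)
  expect_equal(as.vector(table(co$month)), rep(20L, 8L))
  expect_equal(sort(unique(co$bag)), 1:5)
  expect_true(all(co$fatty_acid > 0))
  expect_false(anyDuplicated(co$sample_id) > 0)
})

test_that("noiseless cohort follows the affine trend exactly", {
  co <- generate_cohort(cohort_config(trend_intercept = 8, trend_slope = 1.5,
                                      sample_noise_sd = 0, seed = 1))
  expect_equal(unique(co$fatty_acid[co$month == 3]), 8 + 1.5 * 3)
  expect_equal(as.vector(tapply(co$fatty_acid, co$month, mean)),
               8 + 1.5 * (1:8))
})

test_that("per-month means increase under the default trend", {
  co <- generate_cohort(cohort_config(seed = 11))
  expect_true(all(diff(tapply(co$fatty_acid, co$month, mean)) > 0))
})

test_that("cohorts are bit-reproducible for a fixed seed", {
  a <- generate_cohort(cohort_config(seed = 5))
  b <- generate_cohort(cohort_config(seed = 5))
  d <- generate_cohort(cohort_config(seed = 6))
  expect_identical(a, b)
  expect_false(identical(a$fatty_acid, d$fatty_acid))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(samples_per_month = 1), "samples_per_month")
  expect_error(cohort_config(n_months = 0), "n_months")
  expect_error(cohort_config(sample_noise_sd = -1), "sample_noise_sd")
})

test_that("zero sensitivity and zero noise give identical before/after", {
  sens0 <- sensitivity_matrix(matrix(0, 15, 3), spot_noise_sd = 0)
  pair <- render_sensor_pair(12, sens0, small_geometry(), seed = 2)
  expect_identical(pair$after, pair$before)
})

test_that("overlapping or out-of-bounds spot geometry is rejected", {
  expect_error(sensor_geometry(width = 100, height = 100, spot_radius = 30),
               "overlap")
})

test_that("synthetic spectra live on the 512-point 900-1700 nm grid", {
  sp <- synth_spectrum(15, seed = 4)
  expect_equal(nrow(sp), 512L)
  expect_equal(range(sp$wavelength_nm), c(900, 1700))
  expect_true(all(diff(sp$wavelength_nm) > 0))
})

test_that("degenerate signature yields a flat spectrum at the baseline", {
  sig <- spectral_signature(peak_gains = c(0, 0, 0), bg_heights = c(0, 0),
                            scatter_mult_sd = 0, scatter_add_sd = 0,
                            noise_sd = 0, baseline = 0.37)
  sp <- synth_spectrum(10, sig, seed = 1)
  expect_equal(sp$intensity, rep(0.37, 512))
})

test_that("SG+SNV removes pure multiplicative/additive scatter", {
  sig <- spectral_signature(noise_sd = 0)  # scatter on, point noise off
  a <- preprocess_spectrum(synth_spectrum(14, sig, seed = 1))
  b <- preprocess_spectrum(synth_spectrum(14, sig, seed = 2))
  expect_lt(max(abs(a$intensity - b$intensity)), 1e-9)
})

test_that("cohort modality builders are reproducible and sample-keyed", {
  co <- generate_cohort(cohort_config(n_months = 2, samples_per_month = 4,
                                      n_bags = 2, seed = 9))
  g <- small_geometry()
  F1 <- cohort_sensor_features(co, geometry = g)
  F2 <- cohort_sensor_features(co, geometry = g)
  expect_identical(F1, F2)
  expect_equal(dim(F1), c(8L, 45L))
  S1 <- cohort_spectra(co)
  expect_identical(S1, cohort_spectra(co))
  expect_equal(dim(S1), c(8L, 512L))
})
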