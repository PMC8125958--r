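test_that("SG smoothing reproduces polynomials up to the fit order", {
  x <- seq(900, 1700, length.out = 512)
  flat <- data.frame(wavelength_nm = x, intensity = rep(5, 512))
  expect_equal(sg_smooth(flat)$intensity, flat$intensity)
  quad <- data.frame(wavelength_nm = x,
                     intensity = 2 + 0.003 * x - 1e-6 * x^2)
  expect_lt(max(abs(sg_smooth(quad, 11, 2)$intensity - quad$intensity)), 1e-9)
})

test_that("SG smoothing equals an explicit local least-squares fit", {
  set.seed(3)
  y <- rnorm(60)
  sm <- sg_smooth(y, window = 11, polyorder = 2)
  for (i in c(6, 25, 55)) {
    t <- -5:5
    fit <- lm(y[(i - 5):(i + 5)] ~ t + I(t^2))
    expect_equal(sm[i], unname(coef(fit)[1]), tolerance = 1e-9)
  }
  # edge values come from the terminal window's polynomial fit
  t0 <- 0:10
  fit0 <- lm(y[1:11] ~ t0 + I(t0^2))
  expect_equal(sm[1], unname(coef(fit0)[1]), tolerance = 1e-9)
})

test_that("SG smoothing is linear in the spectrum", {
  set.seed(4)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(sg_smooth(2 * x + 3 * y), 2 * sg_smooth(x) + 3 * sg_smooth(y),
               tolerance = 1e-10)
})

test_that("SG parameter violations are rejected", {
  y <- rnorm(50)
  expect_error(sg_smooth(y, window = 10), "odd")
  expect_error(sg_smooth(y, window = 5, polyorder = 5), "polyorder")
  expect_error(sg_smooth(y[1:5], window = 11), "length")
})

test_that("SNV standardizes to mean 0, sd 1 and is affine-invariant", {
  set.seed(5)
  x <- rnorm(512, 10, 2)
  out <- snv(x)
  expect_lt(abs(mean(out)), 1e-9)
  expect_lt(abs(sd(out) - 1), 1e-9)
  expect_lt(max(abs(snv(3.7 * x + 11) - out)), 1e-9)
  expect_equal(snv(out), out, tolerance = 1e-12)  # idempotent fixed point
  expect_error(snv(rep(1, 100)), "constant")
})

test_that("preprocessing composes SG then SNV and keeps the grid length", {
  sp <- synth_spectrum(12, seed = 8)
  out <- preprocess_spectrum(sp)
  expect_equal(nrow(out), 512L)
  expect_identical(out$wavelength_nm, sp$wavelength_nm)
  expect_equal(out$intensity, snv(sg_smooth(sp))$intensity)
  expect_error(preprocess_spectrum(
    data.frame(wavelength_nm = 1:50, intensity = rep(2, 50))), "constant")
})

test_that("matrix preprocessing matches the per-spectrum path", {
  co <- generate_cohort(cohort_config(n_months = 2, samples_per_month = 2,
                                      n_bags = 1, seed = 2))
  S <- cohort_spectra(co)
  P <- preprocess_spectra(S)
  expect_equal(dim(P), dim(S))
  expect_equal(P[3, ], preprocess_spectrum(
    data.frame(wavelength_nm = attr(S, "wavelengths"),
               intensity = S[3, ]))$intensity,
    ignore_attr = TRUE)
  expect_lt(max(abs(rowMeans(P))), 1e-9)
})
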