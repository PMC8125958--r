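test_that("median filter is identity on constants and window 1", {
  img <- array(37, dim = c(8, 9, 3))
  expect_equal(median_filter(img, 3), img)
  rnd <- array(runif(8 * 9 * 3, 0, 255), dim = c(8, 9, 3))
  expect_identical(median_filter(rnd, 1), rnd)
})

test_that("median filter removes isolated speckle", {
  img <- array(0, dim = c(9, 9, 3))
  img[5, 5, ] <- 255
  filt <- median_filter(img, 3)
  expect_equal(filt[5, 5, ], c(0, 0, 0))
  expect_true(all(filt == 0))
})

test_that("median filter matches an explicit neighborhood-sort oracle", {
  set.seed(42)
  img <- array(sample(0:255, 10 * 11 * 3, replace = TRUE), dim = c(10, 11, 3))
  filt <- median_filter(img, 3)
  for (case in list(c(5, 6), c(2, 2), c(9, 10))) {
    r <- case[1]; cc <- case[2]
    for (ch in 1:3) {
      neigh <- as.vector(img[(r - 1):(r + 1), (cc - 1):(cc + 1), ch])
      expect_equal(filt[r, cc, ch], sort(neigh)[5])
    }
  }
})

test_that("median filter output range never exceeds the input range", {
  set.seed(7)
  img <- array(runif(12 * 12 * 3, 40, 200), dim = c(12, 12, 3))
  for (w in c(3, 5)) {
    filt <- median_filter(img, w)
    expect_gte(min(filt), min(img))
    expect_lte(max(filt), max(img))
  }
})

test_that("even or non-positive filter windows are rejected", {
  img <- array(0, dim = c(5, 5, 3))
  expect_error(median_filter(img, 2), "odd")
  expect_error(median_filter(img, -3), "odd")
})

test_that("segmentation recovers the programmed grid on rendered images", {
  g <- small_geometry()
  pair <- render_sensor_pair(15, sensitivity_matrix(spot_noise_sd = 0), g,
                             seed = 1)
  grid <- segment_spots(pair$before)
  expect_equal(nrow(grid$centers), 15L)
  expect_lt(max(abs(grid$centers - g$centers)), 2)
  # row-major ordering: rows non-decreasing in blocks, cols increasing within
  expect_true(all(diff(grid$centers[c(1, 4, 7, 10, 13), 1]) > 0))
  expect_true(all(diff(grid$centers[1:3, 2]) > 0))
})

test_that("blank images fail segmentation with a zero-region report", {
  blank <- array(128, dim = c(50, 50, 3))
  expect_error(segment_spots(blank), "0 regions")
})

test_that("segmentation reports an unexpected region count", {
  img <- disk_image(60, 60, c(30, 30), 8, c(255, 255, 255))
  expect_error(segment_spots(img), "found 1 region")
})

test_that("mean spot RGB is exact on a uniform disk", {
  img <- disk_image(41, 41, c(21, 21), 12, c(10, 20, 30), background = 200)
  grid <- spot_grid(matrix(rep(c(21, 21), 15), 15, 2, byrow = TRUE),
                    radius = 8)
  m <- mean_spot_rgb(img, grid)
  expect_equal(unname(m[1, ]), c(10, 20, 30))
})

test_that("mean spot RGB matches a brute-force pixel enumeration", {
  # half-0 / half-255 disk split through the center
  img <- disk_image(41, 41, c(21, 21), 12, c(255, 255, 255))
  img[, 1:21, ] <- 0
  grid <- spot_grid(matrix(rep(c(21, 21), 15), 15, 2, byrow = TRUE),
                    radius = 9)
  got <- mean_spot_rgb(img, grid)[1, ]
  vals <- c()
  for (r in 1:41) for (cc in 1:41) {
    if ((r - 21)^2 + (cc - 21)^2 <= 81) vals <- c(vals, img[r, cc, 1])
  }
  expect_equal(unname(got), rep(mean(vals), 3))
})

test_that("a sub-pixel radius reduces the disk to its center pixel", {
  img <- array(runif(21 * 21 * 3, 0, 255), dim = c(21, 21, 3))
  grid <- spot_grid(matrix(rep(c(11, 11), 15), 15, 2, byrow = TRUE),
                    radius = 0.4)
  expect_equal(unname(mean_spot_rgb(img, grid)[1, ]), img[11, 11, ])
})

test_that("disks leaving the image are a geometry error", {
  img <- array(0, dim = c(30, 30, 3))
  grid <- spot_grid(matrix(rep(c(3, 3), 15), 15, 2, byrow = TRUE), radius = 5)
  expect_error(mean_spot_rgb(img, grid), "bounds")
})

test_that("delta components difference the mean matrices row-major", {
  before <- matrix(seq_len(45), 15, 3)
  expect_equal(as.vector(delta_components(before, before)), rep(0, 45))
  after <- before + matrix(1:3, 15, 3, byrow = TRUE)
  d <- delta_components(before, after)
  expect_length(d, 45L)
  expect_equal(as.vector(d), rep(c(1, 2, 3), 15))
  expect_identical(names(d)[1:4], c("s01_dR", "s01_dG", "s01_dB", "s02_dR"))
  expect_error(delta_components(before, before[1:10, ]), "x 3")
})

test_that("zero-noise render/extract round trip recovers programmed shifts", {
  g <- small_geometry()
  sens <- sensitivity_matrix(spot_noise_sd = 0)
  pair <- render_sensor_pair(18, sens, g, seed = 6)
  feats <- extract_color_features(pair$before, pair$after)
  expect_lt(max(abs(feats$raw - as.vector(t(pair$shifts)))), 0.5)
})

test_that("normalization maps each channel to [0, 1] with the degenerate rule", {
  v <- rep(0, 45)
  v[seq(1, 45, 3)[1:3]] <- c(0, 5, 10)  # dR channel spread over 3 spots
  attr(v, "normalized") <- FALSE
  out <- normalize_deltas(v)
  expect_equal(unname(out[seq(1, 45, 3)[1:3]]), c(0, 0.5, 1))
  expect_equal(unname(out[seq(2, 45, 3)]), rep(0.5, 15))  # constant channel
  set.seed(1)
  r <- rnorm(45); attr(r, "normalized") <- FALSE
  rn <- normalize_deltas(r)
  for (ch in 1:3) {
    chan <- rn[seq(ch, 45, 3)]
    expect_equal(unname(range(chan)), c(0, 1))
  }
  expect_error(normalize_deltas(rn), "already")
})

test_that("difference image paints per-spot gray means", {
  g <- small_geometry()
  v <- rep(0, 45)
  v[4:6] <- 1  # spot 2 fully shifted
  attr(v, "normalized") <- TRUE
  img <- difference_image(v, g)
  expect_equal(img[g$centers[2, 1], g$centers[2, 2]], 255)
  expect_equal(img[g$centers[1, 1], g$centers[1, 2]], 0)
  set.seed(2)
  v2 <- runif(45); attr(v2, "normalized") <- TRUE
  img2 <- difference_image(v2, g)
  lv <- 255 * colMeans(matrix(v2, nrow = 3))
  for (s in c(1, 8, 15))
    expect_equal(img2[g$centers[s, 1], g$centers[s, 2]], lv[s])
})
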