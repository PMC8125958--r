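#' Configuration of a synthetic storage cohort
#'
#' Describes the sampling design of the storage experiment the generator
#' emulates: monthly draws of rice samples over a storage period, with the
#' free fatty acid value (mg KOH-equivalent / 100 g) rising linearly with
#' storage month plus sample-to-sample Gaussian scatter.
#'
#' Defaults reproduce the design the pipeline is built around: 8 months x
#' 20 samples/month (5 bags x 4 samples) = 160 samples, with a trend of
#' 8.5 + 1.6 x month so that values span roughly 8.3--21 mg/100 g.
#'
#' @param n_months number of storage months (>= 1).
#' @param samples_per_month samples drawn each month (>= 2).
#' @param n_bags bags the monthly samples are spread over (labelling only).
#' @param trend_intercept,trend_slope affine fatty-acid trend, mg/100 g and
#'   mg/100 g per month.
#' @param sample_noise_sd Gaussian sample scatter, mg/100 g (>= 0).
#' @param seed master seed; spawns one sub-seed per sample.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_months = 8L, samples_per_month = 20L, n_bags = 5L,
                          trend_intercept = 8.5, trend_slope = 1.6,
                          sample_noise_sd = 1.0, seed = 1L) {
  cfg <- list(n_months = as.integer(n_months),
              samples_per_month = as.integer(samples_per_month),
              n_bags = as.integer(n_bags),
              trend_intercept = trend_intercept, trend_slope = trend_slope,
              sample_noise_sd = sample_noise_sd, seed = as.integer(seed))
  if (cfg$n_months < 1L) stop("n_months must be >= 1", call. = FALSE)
  if (cfg$samples_per_month < 2L)
    stop("samples_per_month must be >= 2", call. = FALSE)
  if (cfg$n_bags < 1L || cfg$samples_per_month %% cfg$n_bags != 0L)
    stop("samples_per_month must be a positive multiple of n_bags", call. = FALSE)
  if (cfg$sample_noise_sd < 0) stop("sample_noise_sd must be >= 0", call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic storage cohort
#'
#' Draws `n_months * samples_per_month` rice samples. Each sample's reference
#' fatty-acid value is `trend_intercept + trend_slope * month` plus Gaussian
#' noise, redrawn (truncated) if non-positive. Every sample also carries a
#' deterministically derived `sample_seed` so its sensor images and spectrum
#' can be regenerated independently of the rest of the cohort.
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `sample_id`, `month`, `bag`, `fatty_acid`,
#'   `sample_seed`; the config is attached as attribute `"config"`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' nrow(cohort)  # 160
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_months * config$samples_per_month
  month <- rep(seq_len(config$n_months), each = config$samples_per_month)
  per_bag <- config$samples_per_month %/% config$n_bags
  bag <- rep(rep(seq_len(config$n_bags), each = per_bag), config$n_months)
  within_bag <- rep(rep(seq_len(per_bag), config$n_bags), config$n_months)
  fatty_acid <- with_seed(config$seed, {
    mu <- config$trend_intercept + config$trend_slope * month
    y <- mu + rnorm(n, 0, config$sample_noise_sd)
    for (tries in seq_len(100L)) {
      bad <- y <= 0
      if (!any(bad)) break
      y[bad] <- mu[bad] + rnorm(sum(bad), 0, config$sample_noise_sd)
    }
    if (any(y <= 0))
      stop("could not draw positive fatty-acid values; trend too negative",
           call. = FALSE)
    y
  })
  out <- data.frame(
    sample_id = sprintf("M%02d_B%d_S%d", month, bag, within_bag),
    month = month, bag = bag, fatty_acid = fatty_acid,
    sample_seed = vapply(seq_len(n), function(i) child_seed(config$seed, i),
                         integer(1)),
    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  out
}

#' Sensor-array sensitivity matrix
#'
#' The forward model of the 15-spot colorimetric array: entry (s, c) is the
#' mean shift of channel c (R, G, B) of spot s per unit fatty acid, in 8-bit
#' intensity units per mg/100 g. The default is an arbitrary but fixed pattern
#' drawn once from uniform(-2.5, 2.5); with fatty acid up to ~21 mg/100 g the
#' programmed shifts stay within +/- 55 intensity units, clear of the 0--255
#' clip for the default base colors.
#'
#' @param coefficients 15 x 3 numeric matrix, or NULL for the fixed default.
#' @param spot_noise_sd per-spot-channel Gaussian noise on the shifted color,
#'   intensity units.
#' @return list of class `sensitivity_matrix`.
#' @export
sensitivity_matrix <- function(coefficients = NULL, spot_noise_sd = 1.0) {
  if (is.null(coefficients)) {
    coefficients <- with_seed(20210326L,
                              matrix(runif(45, -2.5, 2.5), 15, 3))
  }
  coefficients <- as.matrix(coefficients)
  if (!all(dim(coefficients) == c(15L, 3L)))
    stop("coefficients must be a 15 x 3 matrix", call. = FALSE)
  if (spot_noise_sd < 0) stop("spot_noise_sd must be >= 0", call. = FALSE)
  structure(list(coefficients = coefficients, spot_noise_sd = spot_noise_sd),
            class = "sensitivity_matrix")
}

#' Sensor-array image geometry
#'
#' Placement of the 5-row x 3-column dye-spot grid on the scanned image.
#' Spot centers sit on a uniform grid with equal margins; the default canvas
#' (360 x 600 px, spot radius 30 px) keeps the 15-px extraction radius well
#' inside every spot and the spots pairwise disjoint.
#'
#' @param width,height image size in pixels (width = columns).
#' @param nrow_spots,ncol_spots grid layout (defaults 5 x 3).
#' @param spot_radius rendered dye-spot radius, pixels.
#' @param background background gray level, 0--255.
#' @param base_colors 15 x 3 matrix of unexposed spot colors (0--255), or NULL
#'   for a fixed default drawn once from uniform(60, 170).
#' @return list of class `sensor_geometry` with a `centers` element: 15 x 2
#'   matrix of (row, col) pixel-center coordinates (1-based), row-major order.
#' @export
sensor_geometry <- function(width = 600L, height = 360L,
                            nrow_spots = 5L, ncol_spots = 3L,
                            spot_radius = 30, background = 245,
                            base_colors = NULL) {
  if (is.null(base_colors)) {
    base_colors <- with_seed(20210327L, matrix(runif(45, 60, 170), 15, 3))
  }
  base_colors <- as.matrix(base_colors)
  n_spots <- nrow_spots * ncol_spots
  if (!all(dim(base_colors) == c(n_spots, 3L)))
    stop("base_colors must be ", n_spots, " x 3", call. = FALSE)
  row_step <- height / nrow_spots
  col_step <- width / ncol_spots
  centers <- as.matrix(expand.grid(
    col = (seq_len(ncol_spots) - 0.5) * col_step,
    row = (seq_len(nrow_spots) - 0.5) * row_step))[, c("row", "col")]
  dimnames(centers) <- list(NULL, c("row", "col"))
  if (min(row_step, col_step) <= 2 * spot_radius)
    stop("spots overlap: grid step ", round(min(row_step, col_step), 1),
         " px <= spot diameter ", 2 * spot_radius, " px", call. = FALSE)
  if (spot_radius >= min(centers) ||
      any(centers[, "row"] + spot_radius > height) ||
      any(centers[, "col"] + spot_radius > width))
    stop("spots exit image bounds", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 nrow_spots = as.integer(nrow_spots),
                 ncol_spots = as.integer(ncol_spots),
                 spot_radius = spot_radius, background = background,
                 base_colors = base_colors, centers = centers),
            class = "sensor_geometry")
}

# linear pixel indices of each spot disk for an h x w canvas
disk_indices <- function(centers, radius, h, w) {
  lapply(seq_len(nrow(centers)), function(s) {
    cr <- centers[s, 1]; cc <- centers[s, 2]
    rows <- max(1L, floor(cr - radius)):min(h, ceiling(cr + radius))
    cols <- max(1L, floor(cc - radius)):min(w, ceiling(cc + radius))
    inside <- outer((rows - cr)^2, (cols - cc)^2, "+") <= radius^2
    idx <- outer(rows, (cols - 1L) * h, "+")
    idx[inside]
  })
}

# render one sensor image: spots of the given colors (15 x 3) on the background
render_array <- function(spot_colors, geometry, idx) {
  h <- geometry$height; w <- geometry$width
  img <- array(NA_real_, dim = c(h, w, 3))
  for (ch in 1:3) {
    M <- matrix(geometry$background, h, w)
    for (s in seq_along(idx)) M[idx[[s]]] <- spot_colors[s, ch]
    img[, , ch] <- M
  }
  img
}

#' Render a before/after sensor-array image pair
#'
#' Inverse model of the image-analysis chain: the "before" image shows the 15
#' unexposed dye spots at their base colors on a uniform background; in the
#' "after" image each spot's color is shifted by
#' `coefficients[spot, channel] * fatty_acid` plus Gaussian spot noise,
#' clipped to the 0--255 scale. Intensities are kept continuous in memory;
#' quantization to whole 8-bit levels happens when images are written to PNG
#' by [write_cohort()].
#'
#' @param fatty_acid sample fatty-acid value, mg/100 g (> 0).
#' @param sens a [sensitivity_matrix()].
#' @param geometry a [sensor_geometry()].
#' @param seed integer seed for the spot noise.
#' @return list with elements `before` and `after`, each a height x width x 3
#'   array on the 0--255 scale, plus the programmed `shifts` (15 x 3).
#' @export
render_sensor_pair <- function(fatty_acid, sens = sensitivity_matrix(),
                               geometry = sensor_geometry(), seed = 1L) {
  stopifnot(inherits(sens, "sensitivity_matrix"),
            inherits(geometry, "sensor_geometry"))
  if (fatty_acid <= 0) stop("fatty_acid must be > 0", call. = FALSE)
  idx <- disk_indices(geometry$centers, geometry$spot_radius,
                      geometry$height, geometry$width)
  shifts <- sens$coefficients * fatty_acid
  noise <- with_seed(seed,
                     matrix(rnorm(length(shifts), 0, sens$spot_noise_sd),
                            nrow(shifts), ncol(shifts)))
  before <- render_array(pmin(pmax(geometry$base_colors, 0), 255),
                         geometry, idx)
  after <- render_array(pmin(pmax(geometry$base_colors + shifts + noise,
                                  0), 255), geometry, idx)
  list(before = before, after = after, shifts = shifts)
}

#' NIR spectral signature of the forward model
#'
#' Statistical stand-in for the grain's near-infrared response: a baseline
#' with fixed (fatty-acid-independent) background absorption bands — by
#' default near the 970 and 1450 nm water bands that dominate grain spectra —
#' plus Gaussian absorption peaks at the lipid C--H bands (defaults 1165,
#' 1215 and 1395 nm) whose heights grow linearly with fatty acid, all
#' distorted by multiplicative and additive scatter and white noise. The
#' fixed background is what lets scatter correction (SNV) keep the analyte
#' signal: the lipid peaks vary against a stable spectral shape, so the
#' standardized spectrum still changes with fatty acid.
#'
#' @param n_points points on the uniform wavelength grid (default 512).
#' @param range_nm wavelength range, nm (default 900--1700).
#' @param peak_centers,peak_widths,peak_gains per-peak center (nm), Gaussian
#'   width (nm) and height gain (absorbance per mg/100 g).
#' @param bg_centers,bg_widths,bg_heights fixed background bands: center
#'   (nm), Gaussian width (nm) and height (absorbance), independent of
#'   fatty acid.
#' @param baseline flat baseline absorbance.
#' @param scatter_mult_sd sd of the multiplicative scatter factor (about 1).
#' @param scatter_add_sd sd of the additive offset, absorbance.
#' @param noise_sd sd of per-point white noise, absorbance.
#' @return list of class `spectral_signature` with the wavelength `grid`.
#' @export
spectral_signature <- function(n_points = 512L, range_nm = c(900, 1700),
                               peak_centers = c(1165, 1215, 1395),
                               peak_widths = c(30, 30, 40),
                               peak_gains = c(0.010, 0.008, 0.012),
                               bg_centers = c(970, 1450),
                               bg_widths = c(45, 65),
                               bg_heights = c(0.08, 0.18),
                               baseline = 0.4,
                               scatter_mult_sd = 0.05, scatter_add_sd = 0.02,
                               noise_sd = 0.002) {
  grid <- seq(range_nm[1], range_nm[2], length.out = n_points)
  stopifnot(length(peak_centers) == length(peak_widths),
            length(peak_centers) == length(peak_gains),
            all(peak_widths > 0),
            length(bg_centers) == length(bg_widths),
            length(bg_centers) == length(bg_heights),
            all(bg_widths > 0),
            scatter_mult_sd >= 0, scatter_add_sd >= 0, noise_sd >= 0)
  if (any(peak_centers < range_nm[1] | peak_centers > range_nm[2]))
    stop("peak centers must lie within the wavelength range", call. = FALSE)
  structure(list(grid = grid, peak_centers = peak_centers,
                 peak_widths = peak_widths, peak_gains = peak_gains,
                 bg_centers = bg_centers, bg_widths = bg_widths,
                 bg_heights = bg_heights,
                 baseline = baseline, scatter_mult_sd = scatter_mult_sd,
                 scatter_add_sd = scatter_add_sd, noise_sd = noise_sd),
            class = "spectral_signature")
}

#' Synthesize one NIR spectrum
#'
#' `intensity(lambda) = m * [baseline + background(lambda) +
#' sum_p gain_p * fatty_acid * exp(-(lambda - center_p)^2 / (2 width_p^2))]
#' + a + noise`, where `background` is the fixed band structure of the
#' signature and `m ~ 1 + N(0, scatter_mult_sd)`, `a ~ N(0, scatter_add_sd)`
#' are drawn once per spectrum. SNV preprocessing removes the (m, a)
#' distortion exactly.
#'
#' @param fatty_acid mg/100 g (> 0).
#' @param signature a [spectral_signature()].
#' @param seed integer seed for scatter and noise.
#' @return data.frame with columns `wavelength_nm`, `intensity`.
#' @export
synth_spectrum <- function(fatty_acid, signature = spectral_signature(),
                           seed = 1L) {
  stopifnot(inherits(signature, "spectral_signature"))
  if (fatty_acid <= 0) stop("fatty_acid must be > 0", call. = FALSE)
  lam <- signature$grid
  clean <- rep(signature$baseline, length(lam))
  for (p in seq_along(signature$bg_centers)) {
    clean <- clean + signature$bg_heights[p] *
      exp(-(lam - signature$bg_centers[p])^2 / (2 * signature$bg_widths[p]^2))
  }
  for (p in seq_along(signature$peak_centers)) {
    clean <- clean + signature$peak_gains[p] * fatty_acid *
      exp(-(lam - signature$peak_centers[p])^2 /
            (2 * signature$peak_widths[p]^2))
  }
  intensity <- with_seed(seed, {
    m <- 1 + rnorm(1, 0, signature$scatter_mult_sd)
    a <- rnorm(1, 0, signature$scatter_add_sd)
    m * clean + a + rnorm(length(lam), 0, signature$noise_sd)
  })
  data.frame(wavelength_nm = lam, intensity = intensity)
}

#' Sensor features for a whole cohort
#'
#' Renders each sample's before/after image pair (using the sample's derived
#' seed) and runs the full extraction chain of [extract_color_features()].
#' The modelling features are the raw per-spot delta components (which are
#' affine in fatty acid); the within-sample normalized vectors used for
#' difference-image rendering are attached as an attribute.
#'
#' @param cohort a cohort data.frame from [generate_cohort()].
#' @param sens,geometry forward-model parameters.
#' @param radius extraction disk radius in pixels (default 15).
#' @param use_segmentation segment spot centers from the before image (the
#'   default); if `FALSE`, or if segmentation fails, the known rendering grid
#'   is used instead.
#' @return n x 45 matrix of raw delta features (rows named by `sample_id`);
#'   the within-sample normalized deltas are attached as attribute
#'   `"normalized"`.
#' @export
cohort_sensor_features <- function(cohort, sens = sensitivity_matrix(),
                                   geometry = sensor_geometry(), radius = 15,
                                   use_segmentation = TRUE) {
  n <- nrow(cohort)
  norm <- matrix(NA_real_, n, 45L)
  raw <- matrix(NA_real_, n, 45L)
  # the unexposed array is sample-independent: filter and segment it once
  idx <- disk_indices(geometry$centers, geometry$spot_radius,
                      geometry$height, geometry$width)
  before <- render_array(pmin(pmax(geometry$base_colors, 0), 255),
                         geometry, idx)
  fb <- median_filter(before)
  grid <- NULL
  if (use_segmentation)
    grid <- tryCatch(segment_spots(fb, radius = radius),
                     error = function(e) NULL)
  if (is.null(grid)) grid <- spot_grid(geometry$centers, radius = radius)
  before_means <- mean_spot_rgb(fb, grid)
  for (i in seq_len(n)) {
    shifts <- sens$coefficients * cohort$fatty_acid[i]
    noise <- with_seed(child_seed(cohort$sample_seed[i], 1L),
                       matrix(rnorm(length(shifts), 0, sens$spot_noise_sd),
                              nrow(shifts), ncol(shifts)))
    after <- render_array(pmin(pmax(geometry$base_colors + shifts + noise,
                                    0), 255), geometry, idx)
    d <- delta_components(before_means, mean_spot_rgb(median_filter(after),
                                                      grid))
    raw[i, ] <- d
    norm[i, ] <- normalize_deltas(d)
  }
  colnames(norm) <- colnames(raw) <- feature_names()
  rownames(norm) <- rownames(raw) <- cohort$sample_id
  attr(raw, "normalized") <- norm
  raw
}

#' Raw NIR spectra for a whole cohort
#'
#' @param cohort a cohort data.frame from [generate_cohort()].
#' @param signature a [spectral_signature()].
#' @return n x n_points intensity matrix (rows named by `sample_id`), with the
#'   wavelength grid attached as attribute `"wavelengths"`.
#' @export
cohort_spectra <- function(cohort, signature = spectral_signature()) {
  n <- nrow(cohort)
  M <- matrix(NA_real_, n, length(signature$grid))
  for (i in seq_len(n)) {
    sp <- synth_spectrum(cohort$fatty_acid[i], signature,
                         seed = child_seed(cohort$sample_seed[i], 2L))
    M[i, ] <- sp$intensity
  }
  rownames(M) <- cohort$sample_id
  attr(M, "wavelengths") <- signature$grid
  M
}
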