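#' @title Sensor-array image analysis
#' @description The image chain that turns a before/after pair of scanned
#'   sensor-array images into the 45-component color feature vector:
#'   median filtering, threshold segmentation of the 15 dye spots, per-spot
#'   mean RGB over fixed-radius disks, after-minus-before deltas, per-channel
#'   min--max normalization, and an optional gray difference image.
#' @name sensor-imaging
NULL

as_rgb_array <- function(img) {
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected a height x width x 3 RGB array", call. = FALSE)
  if (min(img) < 0 || max(img) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  img
}

#' Median-filter an RGB image
#'
#' Each channel is filtered independently with a square window; borders are
#' handled by symmetric (edge-inclusive) reflection padding, so the output
#' range never exceeds the input range.
#'
#' @param img height x width x 3 array, values in `[0, 255]`.
#' @param window odd window side length (default 3); `window = 1` is the
#'   identity.
#' @return filtered array, same shape and scale.
#' @export
median_filter <- function(img, window = 3L) {
  img <- as_rgb_array(img)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1", call. = FALSE)
  if (window == 1L) return(img)
  p <- window %/% 2L
  h <- dim(img)[1]; w <- dim(img)[2]
  if (window > min(h, w)) stop("window exceeds image size", call. = FALSE)
  ridx <- c(p:1, 1:h, h:(h - p + 1L))
  cidx <- c(p:1, 1:w, w:(w - p + 1L))
  out <- img
  for (ch in 1:3) out[, , ch] <- cpp_median_core(img[ridx, cidx, ch], p)
  out
}

#' Spot grid
#'
#' The 15 spot centers of a 5 x 3 sensor array in row-major order (top-left
#' spot first), plus the extraction-disk radius.
#'
#' @param centers 15 x 2 matrix of (row, col) pixel-center coordinates
#'   (1-based).
#' @param radius extraction disk radius in pixels (default 15).
#' @param nrow_spots,ncol_spots grid layout.
#' @return list of class `spot_grid`.
#' @export
spot_grid <- function(centers, radius = 15, nrow_spots = 5L, ncol_spots = 3L) {
  centers <- as.matrix(centers)
  n <- nrow_spots * ncol_spots
  if (nrow(centers) != n || ncol(centers) != 2L)
    stop("centers must be ", n, " x 2", call. = FALSE)
  dimnames(centers) <- list(NULL, c("row", "col"))
  structure(list(centers = centers, radius = radius,
                 nrow_spots = as.integer(nrow_spots),
                 ncol_spots = as.integer(ncol_spots)),
            class = "spot_grid")
}

#' Segment the dye spots of a sensor-array image
#'
#' Threshold segmentation: the image's background color is estimated as the
#' per-channel pixel median; the mean absolute deviation from it (a contrast
#' luminance) is thresholded by Otsu's method; connected foreground components
#' are labelled; components smaller than 20% of the median component area are
#' discarded; the surviving centroids, sorted row-major, become the spot grid.
#'
#' @param img height x width x 3 array, values in `[0, 255]`.
#' @param radius extraction radius stored on the returned grid (default 15).
#' @param nrow_spots,ncol_spots expected grid layout (default 5 x 3).
#' @return a [spot_grid()].
#' @section Errors: if the number of surviving components differs from
#'   `nrow_spots * ncol_spots`, an error reports the count found.
#' @export
segment_spots <- function(img, radius = 15, nrow_spots = 5L, ncol_spots = 3L) {
  img <- as_rgb_array(img)
  n_expected <- nrow_spots * ncol_spots
  bg <- apply(img, 3, median)
  contrast <- (abs(img[, , 1] - bg[1]) + abs(img[, , 2] - bg[2]) +
                 abs(img[, , 3] - bg[3])) / 3 / 255
  if (max(contrast) <= 0)
    stop("segmentation found 0 regions (blank image)", call. = FALSE)
  th <- EBImage::otsu(EBImage::as.Image(contrast), range = c(0, 1))
  labels <- EBImage::bwlabel(contrast > th)
  labels <- matrix(as.integer(labels), nrow(contrast), ncol(contrast))
  n_regions <- max(labels)
  if (n_regions == 0L)
    stop("segmentation found 0 regions (blank image)", call. = FALSE)
  areas <- tabulate(labels[labels > 0L], nbins = n_regions)
  keep <- which(areas >= 0.2 * median(areas))
  if (length(keep) != n_expected)
    stop("segmentation found ", length(keep), " regions, expected ",
         n_expected, call. = FALSE)
  fg <- which(labels > 0L)
  lab_fg <- labels[fg]
  nr <- nrow(labels)
  sums <- rowsum(cbind((fg - 1L) %% nr + 1L, (fg - 1L) %/% nr + 1L),
                 lab_fg, reorder = TRUE)
  centers <- sums[match(keep, sort(unique(lab_fg))), , drop = FALSE] /
    areas[keep]
  # row-major sort: order by row, cut into grid rows, sort each by column
  ord <- order(centers[, 1])
  centers <- centers[ord, , drop = FALSE]
  for (r in seq_len(nrow_spots)) {
    idx <- (r - 1L) * ncol_spots + seq_len(ncol_spots)
    centers[idx, ] <- centers[idx, , drop = FALSE][order(centers[idx, 2]), ]
  }
  spot_grid(centers, radius = radius, nrow_spots = nrow_spots,
            ncol_spots = ncol_spots)
}

#' Mean RGB over each spot disk
#'
#' Entry (s, c) is the arithmetic mean of channel c over all pixels whose
#' center lies within Euclidean distance `radius` (inclusive) of spot center
#' s, in pixel-center coordinates.
#'
#' @param img height x width x 3 array, values in `[0, 255]`.
#' @param grid a [spot_grid()].
#' @return 15 x 3 matrix of channel means (columns R, G, B).
#' @export
mean_spot_rgb <- function(img, grid) {
  img <- as_rgb_array(img)
  stopifnot(inherits(grid, "spot_grid"))
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- grid$radius
  out <- matrix(NA_real_, nrow(grid$centers), 3L,
                dimnames = list(NULL, c("R", "G", "B")))
  for (s in seq_len(nrow(grid$centers))) {
    cr <- grid$centers[s, 1]; cc <- grid$centers[s, 2]
    if (cr - r < 1 || cr + r > h || cc - r < 1 || cc + r > w)
      stop("extraction disk for spot ", s, " exits image bounds", call. = FALSE)
    rows <- floor(cr - r):ceiling(cr + r)
    cols <- floor(cc - r):ceiling(cc + r)
    inside <- outer((rows - cr)^2, (cols - cc)^2, "+") <= r^2
    for (ch in 1:3) out[s, ch] <- mean(img[rows, cols, ch][inside])
  }
  out
}

feature_names <- function(n_spots = 15L) {
  as.vector(t(outer(sprintf("s%02d", seq_len(n_spots)),
                    c("dR", "dG", "dB"), paste, sep = "_")))
}

#' Per-spot color deltas
#'
#' The after-minus-before differences of the per-spot channel means,
#' flattened row-major (spot 1 dR, dG, dB, spot 2 dR, ...) into the
#' 45-component raw color feature vector.
#'
#' @param before_means,after_means 15 x 3 matrices from [mean_spot_rgb()].
#' @return named numeric vector of length 45 with attribute
#'   `normalized = FALSE`.
#' @export
delta_components <- function(before_means, after_means) {
  before_means <- as.matrix(before_means); after_means <- as.matrix(after_means)
  if (!all(dim(before_means) == dim(after_means)) ||
      ncol(before_means) != 3L)
    stop("before/after means must both be n_spots x 3", call. = FALSE)
  d <- after_means - before_means
  v <- as.vector(t(d))
  names(v) <- feature_names(nrow(d))
  attr(v, "normalized") <- FALSE
  v
}

#' Normalize a raw delta vector
#'
#' Per-channel min--max scaling across the 15 spots to `[0, 1]`: all dR
#' components are scaled together, likewise dG and dB. A degenerate channel
#' (max = min) maps to 0.5 everywhere.
#'
#' @param v raw vector from [delta_components()].
#' @return named numeric vector in `[0, 1]` with attribute `normalized = TRUE`.
#' @export
normalize_deltas <- function(v) {
  if (isTRUE(attr(v, "normalized")))
    stop("vector is already normalized", call. = FALSE)
  if (length(v) %% 3L != 0L) stop("length must be a multiple of 3", call. = FALSE)
  out <- v
  for (ch in 1:3) {
    idx <- seq(ch, length(v), by = 3L)
    lo <- min(v[idx]); hi <- max(v[idx])
    out[idx] <- if (hi > lo) (v[idx] - lo) / (hi - lo) else 0.5
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Gray difference image
#'
#' Visualization of a normalized feature vector: each spot is drawn as a gray
#' disk at level `255 * mean(dR', dG', dB')` on a black background, at the
#' positions of the supplied geometry.
#'
#' @param v normalized vector from [normalize_deltas()].
#' @param geometry a [sensor_geometry()].
#' @return height x width grayscale matrix on the 0--255 scale.
#' @export
difference_image <- function(v, geometry = sensor_geometry()) {
  if (!isTRUE(attr(v, "normalized")))
    stop("difference_image expects a normalized vector", call. = FALSE)
  levels <- 255 * colMeans(matrix(v, nrow = 3L))
  img <- matrix(0, geometry$height, geometry$width)
  for (s in seq_along(levels)) {
    ctr <- geometry$centers[s, ]
    rows <- max(1L, floor(ctr[1] - geometry$spot_radius)):
      min(geometry$height, ceiling(ctr[1] + geometry$spot_radius))
    cols <- max(1L, floor(ctr[2] - geometry$spot_radius)):
      min(geometry$width, ceiling(ctr[2] + geometry$spot_radius))
    inside <- outer((rows - ctr[1])^2, (cols - ctr[2])^2, "+") <=
      geometry$spot_radius^2
    sub <- img[rows, cols]
    sub[inside] <- levels[s]
    img[rows, cols] <- sub
  }
  img
}

#' Full extraction chain for one image pair
#'
#' Median-filters both images, locates the spot grid (segmented from the
#' filtered before image unless one is supplied), extracts per-spot channel
#' means from both, and returns raw and normalized delta vectors.
#'
#' @param before,after height x width x 3 arrays, values in `[0, 255]`.
#' @param window median-filter window (default 3).
#' @param radius extraction disk radius (default 15).
#' @param grid optional [spot_grid()]; if NULL the grid is segmented from the
#'   filtered before image.
#' @return list with `raw`, `normalized` (length-45 vectors) and the `grid`.
#' @export
extract_color_features <- function(before, after, window = 3L, radius = 15,
                                   grid = NULL) {
  fb <- median_filter(before, window)
  fa <- median_filter(after, window)
  if (is.null(grid)) grid <- segment_spots(fb, radius = radius)
  raw <- delta_components(mean_spot_rgb(fb, grid), mean_spot_rgb(fa, grid))
  list(raw = raw, normalized = normalize_deltas(raw), grid = grid)
}
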