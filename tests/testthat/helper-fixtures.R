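# Shared fixtures: a reduced-canvas geometry so imaging tests run in
# milliseconds, and small constructed datasets with known structure.

small_geometry <- function(spot_radius = 20, ...) {
  sensor_geometry(width = 210L, height = 250L, spot_radius = spot_radius, ...)
}

# n x p matrix whose response depends only on the first two high-variance
# directions; remaining columns are low-variance noise
two_signal_data <- function(n = 40L, p = 8L, noise = 0.05, seed = 1L) {
  set.seed(seed)
  u1 <- rnorm(n, 0, 3)
  u2 <- rnorm(n, 0, 2)
  X <- cbind(u1, u2, matrix(rnorm(n * (p - 2L), 0, 0.2), n, p - 2L))
  y <- 12 + 1.5 * u1 - 0.8 * u2 + rnorm(n, 0, noise)
  list(X = X, y = y)
}

# uniform RGB image with one centered disk of the given color
disk_image <- function(h, w, center, radius, color, background = 0) {
  img <- array(background, dim = c(h, w, 3))
  for (ch in 1:3) {
    M <- img[, , ch]
    for (r in 1:h) for (cc in 1:w) {
      if ((r - center[1])^2 + (cc - center[2])^2 <= radius^2)
        M[r, cc] <- color[ch]
    }
    img[, , ch] <- M
  }
  img
}
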