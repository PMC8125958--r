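#' Principal component analysis
#'
#' Mean-centers the training matrix and extracts the leading `k` orthonormal
#' loading directions of its covariance (computed via singular value
#' decomposition of the centered matrix, which is numerically equivalent to
#' the covariance eigendecomposition). Components are ordered by decreasing
#' explained variance; each loading's sign is fixed so that its
#' largest-magnitude entry is positive.
#'
#' The explained-variance ratio (EVR; the "covariance contribution rate" of
#' each component) is reported for the retained components, and for all
#' components as attribute-free element `evr_all` so cumulative contribution
#' curves can be drawn.
#'
#' @param X numeric matrix, samples x features, no missing values.
#' @param k number of components, `1 <= k <= min(nrow(X) - 1, ncol(X))`.
#' @return list of class `pca_model`: `mean` (length p), `loadings` (p x k,
#'   orthonormal columns), `explained_variance_ratio` (length k), `evr_all`,
#'   `sdev_all`, and `k`.
#' @examples
#' X <- matrix(rnorm(50), 10, 5)
#' m <- pca_fit(X, 2)
#' crossprod(m$loadings)  # ~ identity
#' @export
pca_fit <- function(X, k) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, p))
    stop("k must satisfy 1 <= k <= min(samples - 1, features)", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  dec <- svd(Xc)
  ev <- dec$d^2 / (n - 1)  # covariance eigenvalues
  total <- sum(ev)
  if (total <= 0) stop("constant matrix: no variance to decompose", call. = FALSE)
  loadings <- dec$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- colnames(X)
  structure(list(mean = mu, loadings = loadings,
                 explained_variance_ratio = ev[seq_len(k)] / total,
                 evr_all = ev / total, sdev_all = sqrt(ev), k = k),
            class = "pca_model")
}

#' Project data onto a fitted PCA basis
#'
#' Scores are `(X - mean) %*% loadings`; training-set scores have zero column
#' means by construction.
#'
#' @param model a [pca_fit()] result.
#' @param X matrix with the same feature dimension as the training data.
#' @return samples x k score matrix.
#' @export
pca_transform <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    stop("feature dimension (", ncol(X), ") does not match the model (",
         length(model$mean), ")", call. = FALSE)
  sweep(X, 2, model$mean) %*% model$loadings
}
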