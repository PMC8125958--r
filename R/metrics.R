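#' Pearson correlation between reference and predicted values
#'
#' @param y,y_hat numeric vectors of equal length >= 2; both non-constant.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 2L)
    stop("y and y_hat must have equal length >= 2", call. = FALSE)
  if (sd(y) == 0 || sd(y_hat) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  cor(y, y_hat)
}

#' Root mean square error
#'
#' @param y,y_hat numeric vectors of equal length >= 1.
#' @return RMSE in the units of `y` (mg/100 g for fatty acid).
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 1L)
    stop("y and y_hat must have equal, positive length", call. = FALSE)
  sqrt(mean((y - y_hat)^2))
}

#' Cross-validated calibration metrics
#'
#' Randomly assigns samples to `folds` folds (from `seed`), trains a BPNN on
#' each training fold and predicts the held-out fold; R_C and RMSECV are
#' computed on the pooled out-of-fold predictions. When `k` is given, a PCA
#' feature reducer with `k` components is refit inside each training fold and
#' applied to its held-out fold, so no test information leaks into the
#' reduction. BPNN initialization seeds are derived per fold from `seed`.
#'
#' @param X feature matrix (raw features when `k` is given, otherwise used
#'   as-is, e.g. precomputed scores).
#' @param y response vector, mg/100 g.
#' @param config a [bpnn_config()].
#' @param folds number of folds (default 5), `2 <= folds <= n`.
#' @param seed seed for fold assignment and per-fold network seeds.
#' @param k optional PCA component count to refit per fold.
#' @return list: `r` (R_C), `rmse` (RMSECV), `predictions` (pooled,
#'   in input order), `fold` assignment.
#' @export
cross_validate <- function(X, y, config = bpnn_config(), folds = 5L,
                           seed = 1L, k = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  folds <- as.integer(folds)
  if (folds < 2L || folds > n)
    stop("folds must satisfy 2 <= folds <= n", call. = FALSE)
  assignment <- with_seed(child_seed(seed, 0L),
                          sample(rep(seq_len(folds), length.out = n)))
  preds <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    test <- assignment == f
    Xtr <- X[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (!is.null(k)) {
      red <- pca_fit(Xtr, k)
      Xtr <- pca_transform(red, Xtr)
      Xte <- pca_transform(red, Xte)
    }
    m <- bpnn_train(Xtr, y[!test], config, seed = child_seed(seed, f))
    preds[test] <- bpnn_predict(m, Xte)
  }
  list(r = pearson_r(y, preds), rmse = rmse(y, preds),
       predictions = preds, fold = assignment)
}

#' Repeated-run statistics
#'
#' Runs a seeded procedure `n_runs` times with distinct seeds derived from
#' `master_seed` and summarizes each returned metric by its mean, sample
#' variance and standard deviation — the repeated-run protocol that averages
#' out the randomness of network weight initialization.
#'
#' @param procedure `function(seed)` returning a named numeric vector of
#'   metrics.
#' @param n_runs number of runs (default 50, >= 2).
#' @param master_seed seed from which the per-run seeds are derived.
#' @return list of class `run_stats`: `stats` (data.frame with metric, mean,
#'   var, sd), `values` (n_runs x metrics matrix), `n_runs`, `seeds`.
#' @export
repeat_runs <- function(procedure, n_runs = 50L, master_seed = 1L) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) stop("n_runs must be >= 2", call. = FALSE)
  seeds <- vapply(seq_len(n_runs), function(r) child_seed(master_seed, r),
                  integer(1))
  first <- procedure(seeds[1])
  values <- matrix(NA_real_, n_runs, length(first),
                   dimnames = list(NULL, names(first)))
  values[1, ] <- first
  for (r in seq_len(n_runs)[-1]) values[r, ] <- procedure(seeds[r])
  stats <- data.frame(metric = colnames(values),
                      mean = unname(colMeans(values)),
                      var = unname(apply(values, 2, var)),
                      sd = unname(apply(values, 2, sd)),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(stats = stats, values = values, n_runs = n_runs,
                 seeds = seeds),
            class = "run_stats")
}
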