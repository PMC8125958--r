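#' Monthly-stratified calibration/prediction split
#'
#' Within each storage month, samples are split at random into training
#' (calibration) and test (prediction) sets at `train_frac` (default 3:1, so
#' 20 monthly samples give 15 training + 5 test, and the default cohort gives
#' 120/40). The training count is rounded to the nearest integer, kept at
#' least as large as the test count, and every month keeps at least one test
#' sample.
#'
#' @param cohort cohort data.frame with `month` (and one row per sample).
#' @param train_frac training fraction within each month (default 0.75).
#' @param seed split seed.
#' @return list with integer row indices `train` and `test` (disjoint,
#'   exhaustive) and the `seed`.
#' @export
split_by_month <- function(cohort, train_frac = 0.75, seed = 1L) {
  stopifnot(is.data.frame(cohort), "month" %in% names(cohort))
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1)", call. = FALSE)
  train <- integer(0)
  for (m in sort(unique(cohort$month))) {
    idx <- which(cohort$month == m)
    n_m <- length(idx)
    if (n_m < 2L)
      stop("month ", m, " has fewer than 2 samples", call. = FALSE)
    n_tr <- round(train_frac * n_m)
    n_tr <- max(n_tr, n_m - n_tr)   # train >= test
    n_tr <- min(n_tr, n_m - 1L)     # at least one test sample
    picked <- with_seed(child_seed(seed, m), sample(idx, n_tr))
    train <- c(train, picked)
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(cohort)), train),
       seed = as.integer(seed))
}

#' Pick the best component count from an RMSECV table
#'
#' Argmin of the mean RMSECV; ties (within `tol`) go to the smaller k.
#'
#' @param table data.frame with columns `k` and `rmsecv_mean`.
#' @param tol absolute tie tolerance (default 0: exact ties only).
#' @return the chosen k (integer).
#' @export
choose_best_k <- function(table, tol = 0) {
  stopifnot(all(c("k", "rmsecv_mean") %in% names(table)))
  best <- min(table$rmsecv_mean)
  as.integer(min(table$k[table$rmsecv_mean <= best + tol]))
}

#' Optimize the number of principal components for one modality
#'
#' For each candidate k, runs `n_runs` repeated cross-validations (fresh fold
#' assignments and network seeds per run, shared across k so comparisons are
#' paired) with the PCA reducer refit inside every training fold, and records
#' the mean RMSECV and R_C. The chosen k minimizes mean RMSECV, ties broken
#' toward the smaller k.
#'
#' @param X training-set feature matrix (45 sensor columns or 512
#'   preprocessed spectral points).
#' @param y training-set fatty-acid values.
#' @param config a [bpnn_config()].
#' @param k_range candidate component counts (default 1:10).
#' @param folds cross-validation folds (default 5).
#' @param n_runs repeated runs per k (default 50).
#' @param seed master seed for the run/fold/network seed streams.
#' @return list: `chosen_k`, `table` (k, rmsecv mean/var/sd, r_c mean/sd),
#'   `values` (n_runs x k matrix of RMSECV draws).
#' @export
optimize_pc_count <- function(X, y, config = bpnn_config(), k_range = 1:10,
                              folds = 5L, n_runs = 50L, seed = 1L) {
  X <- as.matrix(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("k_range must be non-empty", call. = FALSE)
  k_max_feasible <- min(nrow(X) - ceiling(nrow(X) / folds) - 1L, ncol(X))
  if (max(k_range) > k_max_feasible)
    stop("largest k (", max(k_range), ") infeasible for ", nrow(X),
         " samples in ", folds, "-fold CV", call. = FALSE)
  rmsecv <- matrix(NA_real_, n_runs, length(k_range),
                   dimnames = list(NULL, paste0("k", k_range)))
  r_c <- rmsecv
  for (run in seq_len(n_runs)) {
    run_seed <- child_seed(seed, run)
    for (j in seq_along(k_range)) {
      cv <- cross_validate(X, y, config, folds = folds, seed = run_seed,
                           k = k_range[j])
      rmsecv[run, j] <- cv$rmse
      r_c[run, j] <- cv$r
    }
  }
  table <- data.frame(k = k_range,
                      rmsecv_mean = colMeans(rmsecv),
                      rmsecv_var = apply(rmsecv, 2, var),
                      rmsecv_sd = apply(rmsecv, 2, sd),
                      r_c_mean = colMeans(r_c),
                      r_c_sd = apply(r_c, 2, sd),
                      row.names = NULL)
  list(chosen_k = choose_best_k(table), table = table, values = rmsecv)
}

#' Fuse score blocks at the feature level
#'
#' Horizontally concatenates row-aligned PC score blocks from the two
#' instruments and z-scores every column with the training rows' mean and
#' standard deviation, putting the blocks on a common scale before the fused
#' calibrator is trained.
#'
#' @param sensor_scores,nir_scores score matrices over the same samples
#'   (either may have zero columns).
#' @param train_idx integer row indices of the training set.
#' @return list: `features` (n x (k1 + k2) matrix), `center`, `scale`.
#' @export
fuse_scores <- function(sensor_scores, nir_scores, train_idx) {
  sensor_scores <- as.matrix(sensor_scores)
  nir_scores <- as.matrix(nir_scores)
  if (nrow(sensor_scores) != nrow(nir_scores))
    stop("score blocks must have the same rows", call. = FALSE)
  fused <- cbind(sensor_scores, nir_scores)
  if (ncol(fused) == 0L) stop("no columns to fuse", call. = FALSE)
  center <- colMeans(fused[train_idx, , drop = FALSE])
  scale <- apply(fused[train_idx, , drop = FALSE], 2, sd)
  scale[scale <= 0] <- 1
  features <- sweep(sweep(fused, 2, center), 2, scale, "/")
  colnames(features) <- c(
    if (ncol(sensor_scores)) paste0("sensor_pc", seq_len(ncol(sensor_scores))),
    if (ncol(nir_scores)) paste0("nir_pc", seq_len(ncol(nir_scores))))
  list(features = features, center = center, scale = scale)
}

#' Full experiment configuration
#'
#' Bundles every tunable of [run_full_experiment()] with the study defaults:
#' the 160-sample cohort, the sensor and spectral forward models, the default
#' image geometry, SG window 11 / order 2, the 5-node BPNN, 5-fold CV, a PC
#' scan over 1..10, and 50 repeated runs.
#'
#' @param cohort,sensitivity,signature,geometry forward-model settings.
#' @param sg_window,sg_polyorder spectral preprocessing settings.
#' @param bpnn a [bpnn_config()].
#' @param train_frac monthly training fraction (default 0.75).
#' @param folds,k_range,n_runs model-selection protocol.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              sensitivity = sensitivity_matrix(),
                              signature = spectral_signature(),
                              geometry = sensor_geometry(),
                              sg_window = 11L, sg_polyorder = 2L,
                              bpnn = bpnn_config(),
                              train_frac = 0.75, folds = 5L,
                              k_range = 1:10, n_runs = 50L) {
  structure(list(cohort = cohort, sensitivity = sensitivity,
                 signature = signature, geometry = geometry,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 bpnn = bpnn, train_frac = train_frac,
                 folds = as.integer(folds), k_range = as.integer(k_range),
                 n_runs = as.integer(n_runs)),
            class = "experiment_config")
}

# one evaluation run: fit on the training rows, score both subsets
technique_run <- function(X, y, split, config) {
  function(seed) {
    m <- bpnn_train(X[split$train, , drop = FALSE], y[split$train], config,
                    seed = seed)
    p_tr <- bpnn_predict(m, X[split$train, , drop = FALSE])
    p_te <- bpnn_predict(m, X[split$test, , drop = FALSE])
    c(r_c = pearson_r(y[split$train], p_tr),
      rmsec = rmse(y[split$train], p_tr),
      r_p = pearson_r(y[split$test], p_te),
      rmsep = rmse(y[split$test], p_te))
  }
}

#' Run the full fusion experiment
#'
#' Executes the whole study on a synthetic cohort: generate samples, render
#' and extract sensor features, synthesize and preprocess spectra, split by
#' month at 3:1, optimize the PC count of each modality by minimum mean
#' RMSECV over repeated cross-validations, evaluate each single-modality BPNN
#' and the fused-feature BPNN over the same repeated-run seed sequence, and
#' assemble the three-row comparison report. All PCA models and scalers are
#' fitted on training rows only; test rows are only ever transformed.
#'
#' @param config an [experiment_config()].
#' @param seed master seed; every random stage derives its stream from it.
#' @param features,spectra optional precomputed modality matrices (rows
#'   aligned with the cohort): the 45-column normalized sensor features and
#'   the raw spectra. When supplied they replace the rendering/synthesis
#'   steps (used to feed real instrument data through the same pipeline).
#' @param cohort optional precomputed cohort data.frame.
#' @return list of class `fusion_report`: `report` (one row per technique
#'   with PC counts and R_C/RMSEC/R_P/RMSEP means, variances and sds),
#'   `chosen_k`, `pc_tables`, `evr` (per-modality explained-variance ratios),
#'   `split`, `run_seeds`, `cohort`, `config`, `seed`.
#' @export
run_full_experiment <- function(config = experiment_config(), seed = 1L,
                                cohort = NULL, features = NULL,
                                spectra = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cohort)) {
    ccfg <- config$cohort
    ccfg$seed <- child_seed(seed, 1L)
    cohort <- generate_cohort(ccfg)
  }
  y <- cohort$fatty_acid
  if (is.null(features))
    features <- cohort_sensor_features(cohort, config$sensitivity,
                                       config$geometry)
  if (is.null(spectra))
    spectra <- cohort_spectra(cohort, config$signature)
  spectra_pp <- preprocess_spectra(spectra, config$sg_window,
                                   config$sg_polyorder)

  split <- split_by_month(cohort, config$train_frac,
                          seed = child_seed(seed, 2L))
  tr <- split$train

  opt_sensor <- optimize_pc_count(features[tr, , drop = FALSE], y[tr],
                                  config$bpnn, config$k_range, config$folds,
                                  config$n_runs, seed = child_seed(seed, 3L))
  opt_nir <- optimize_pc_count(spectra_pp[tr, , drop = FALSE], y[tr],
                               config$bpnn, config$k_range, config$folds,
                               config$n_runs, seed = child_seed(seed, 4L))

  pca_sensor <- pca_fit(features[tr, , drop = FALSE], opt_sensor$chosen_k)
  pca_nir <- pca_fit(spectra_pp[tr, , drop = FALSE], opt_nir$chosen_k)
  scores_sensor <- pca_transform(pca_sensor, features)
  scores_nir <- pca_transform(pca_nir, spectra_pp)
  fused <- fuse_scores(scores_sensor, scores_nir, tr)

  eval_seed <- child_seed(seed, 5L)
  stats <- list(
    sensor = repeat_runs(technique_run(scores_sensor, y, split, config$bpnn),
                         config$n_runs, eval_seed),
    nir = repeat_runs(technique_run(scores_nir, y, split, config$bpnn),
                      config$n_runs, eval_seed),
    fusion = repeat_runs(technique_run(fused$features, y, split, config$bpnn),
                         config$n_runs, eval_seed))

  pcs <- c(sensor = opt_sensor$chosen_k, nir = opt_nir$chosen_k,
           fusion = opt_sensor$chosen_k + opt_nir$chosen_k)
  report <- do.call(rbind, lapply(names(stats), function(tech) {
    s <- stats[[tech]]$stats
    row <- data.frame(technique = tech, pcs = pcs[[tech]])
    for (i in seq_len(nrow(s))) {
      row[[paste0(s$metric[i], "_mean")]] <- s$mean[i]
      row[[paste0(s$metric[i], "_var")]] <- s$var[i]
      row[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
    }
    row
  }))

  structure(list(report = report, chosen_k = pcs,
                 pc_tables = list(sensor = opt_sensor$table,
                                  nir = opt_nir$table),
                 evr = list(sensor = pca_sensor$evr_all,
                            nir = pca_nir$evr_all),
                 stats = stats, split = split,
                 run_seeds = stats$sensor$seeds, cohort = cohort,
                 config = config, seed = as.integer(seed)),
            class = "fusion_report")
}

#' @export
print.fusion_report <- function(x, ...) {
  cat("Fusion experiment report (", nrow(x$cohort), " samples, ",
      length(x$split$train), " train / ", length(x$split$test), " test, ",
      x$config$n_runs, " runs)\n\n", sep = "")
  df <- x$report[, c("technique", "pcs", "r_c_mean", "rmsec_mean",
                     "r_p_mean", "rmsep_mean")]
  names(df) <- c("technique", "PCs", "R_C", "RMSEC", "R_P", "RMSEP")
  df[, 3:6] <- round(df[, 3:6], 4)
  print(df, row.names = FALSE)
  invisible(x)
}
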