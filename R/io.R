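#' @title On-disk cohort layout and model serialization
#' @description A cohort directory holds `manifest.csv` (the single source of
#'   truth linking files), per-sample before/after PNG images under `images/`,
#'   and per-sample spectrum CSVs under `spectra/`. Models are serialized as
#'   structured JSON.
#' @name cohort-io
NULL

#' Write a synthetic cohort to disk
#'
#' Renders every sample's image pair and spectrum and writes the directory
#' layout described in [cohort-io].
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param sens,signature,geometry forward-model parameters.
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, sens = sensitivity_matrix(),
                         signature = spectral_signature(),
                         geometry = sensor_geometry()) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort
  manifest$before_png <- file.path("images", paste0(cohort$sample_id, "_before.png"))
  manifest$after_png <- file.path("images", paste0(cohort$sample_id, "_after.png"))
  manifest$spectrum_csv <- file.path("spectra", paste0(cohort$sample_id, ".csv"))
  for (i in seq_len(nrow(cohort))) {
    pair <- render_sensor_pair(cohort$fatty_acid[i], sens, geometry,
                               seed = child_seed(cohort$sample_seed[i], 1L))
    png::writePNG(pair$before / 255, file.path(dir, manifest$before_png[i]))
    png::writePNG(pair$after / 255, file.path(dir, manifest$after_png[i]))
    sp <- synth_spectrum(cohort$fatty_acid[i], signature,
                         seed = child_seed(cohort$sample_seed[i], 2L))
    write.csv(sp, file.path(dir, manifest$spectrum_csv[i]), row.names = FALSE)
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return manifest data.frame; the directory is attached as attribute `"dir"`.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv under ", dir, call. = FALSE)
  manifest <- read.csv(path, stringsAsFactors = FALSE)
  attr(manifest, "dir") <- dir
  manifest
}

#' Read an 8-bit RGB PNG as a 0--255 array
#'
#' @param path PNG file path.
#' @return height x width x 3 array on the 0--255 scale.
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L)
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  round(as_rgb_array(img * 255))
}

#' Extract sensor features for every sample of an on-disk cohort
#'
#' Reads each before/after pair named in the manifest and runs
#' [extract_color_features()]; segmentation failures fall back to `grid`
#' when one is supplied.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param window median-filter window.
#' @param radius extraction disk radius.
#' @param grid optional fallback [spot_grid()].
#' @return data.frame: `sample_id` plus the 45 raw delta feature columns
#'   (`s01_dR` ... `s15_dB`).
#' @export
extract_manifest_features <- function(manifest, window = 3L, radius = 15,
                                      grid = NULL) {
  dir <- attr(manifest, "dir")
  M <- matrix(NA_real_, nrow(manifest), 45L,
              dimnames = list(NULL, feature_names()))
  for (i in seq_len(nrow(manifest))) {
    before <- read_rgb_png(file.path(dir, manifest$before_png[i]))
    after <- read_rgb_png(file.path(dir, manifest$after_png[i]))
    feats <- tryCatch(
      extract_color_features(before, after, window = window, radius = radius),
      error = function(e) {
        if (is.null(grid)) stop(e)
        extract_color_features(before, after, window = window,
                               radius = radius, grid = grid)
      })
    M[i, ] <- feats$raw
  }
  cbind(data.frame(sample_id = manifest$sample_id, stringsAsFactors = FALSE),
        as.data.frame(M))
}

#' Read and stack the spectra of an on-disk cohort
#'
#' @param manifest data.frame from [read_manifest()].
#' @return n x p intensity matrix with attribute `"wavelengths"`.
#' @export
read_manifest_spectra <- function(manifest) {
  dir <- attr(manifest, "dir")
  first <- read.csv(file.path(dir, manifest$spectrum_csv[1]))
  M <- matrix(NA_real_, nrow(manifest), nrow(first))
  M[1, ] <- first$intensity
  for (i in seq_len(nrow(manifest))[-1])
    M[i, ] <- read.csv(file.path(dir, manifest$spectrum_csv[i]))$intensity
  rownames(M) <- manifest$sample_id
  attr(M, "wavelengths") <- first$wavelength_nm
  M
}

#' Save / load fitted models as JSON
#'
#' Serializes a [pca_fit()] or [bpnn_train()] model (weights, scalers and
#' configuration) to structured JSON, and restores it.
#'
#' @param model a `pca_model` or `bpnn_model`.
#' @param path output file.
#' @return `save_model()`: the path, invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  type <- class(model)[1]
  if (!type %in% c("pca_model", "bpnn_model"))
    stop("can only serialize pca_model or bpnn_model objects", call. = FALSE)
  payload <- unclass(model)
  if (type == "bpnn_model") payload$config <- unclass(payload$config)
  jsonlite::write_json(list(type = type, model = payload), path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$model
  if (obj$type == "pca_model") {
    m$loadings <- as.matrix(m$loadings)
    m$k <- as.integer(m$k)
  } else {
    m$W <- lapply(m$W, as.matrix)
    m$b <- lapply(m$b, as.numeric)
    m$config <- do.call(bpnn_config, m$config[c("hidden_layers",
                                                "learning_rate",
                                                "max_iterations",
                                                "target_rmse", "seed")])
  }
  class(m) <- obj$type
  m
}

#' Write the Table-2-style report and its companion tables
#'
#' Emits `fusion_report.csv` (one row per technique), per-modality RMSECV
#' curves (`pc_scan_<modality>.csv`) and explained-variance tables
#' (`evr_<modality>.csv`) under `dir`.
#'
#' @param result a [run_full_experiment()] result.
#' @param dir output directory.
#' @return vector of written paths, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "fusion_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "fusion_report.csv")
  write.csv(result$report, paths[1], row.names = FALSE)
  for (mod in names(result$pc_tables)) {
    p <- file.path(dir, paste0("pc_scan_", mod, ".csv"))
    write.csv(result$pc_tables[[mod]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (mod in names(result$evr)) {
    evr <- result$evr[[mod]]
    p <- file.path(dir, paste0("evr_", mod, ".csv"))
    write.csv(data.frame(pc = seq_along(evr), evr = evr,
                         cumulative_evr = cumsum(evr)),
              p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
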