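#!/usr/bin/env Rscript
# Stage 4 — the fusion experiment.
#
# Monthly-stratified 3:1 split, per-modality PC-count optimization by minimum
# mean RMSECV over 50 repeated 5-fold cross-validations, then 50 evaluation
# runs of the sensor, NIR and fused-feature BPNN models on the same split and
# seed sequence. Consumes the stage 1-2 outputs; spectra are preprocessed
# inside the pipeline (SG + SNV, as in stage 3). Writes the three-row
# comparison report, the per-k RMSECV scans and the explained-variance tables
# under results/.

suppressPackageStartupMessages(library(ricefusion))

seed <- 20260923L
manifest <- read_manifest("results/cohort")
features <- as.matrix(read.csv("results/features_sensor.csv")[, -1])
spectra <- read_manifest_spectra(manifest)

res <- run_full_experiment(experiment_config(), seed = seed,
                           cohort = manifest, features = features,
                           spectra = spectra)
write_report(res, "results")
print(res)

cat("\nPer-modality PC scans (mean RMSECV over 50 runs):\n")
for (mod in names(res$pc_tables)) {
  tab <- res$pc_tables[[mod]]
  cat(sprintf("  %s: best k = %d (RMSECV %.4f mg/100 g)\n", mod,
              res$chosen_k[[mod]], min(tab$rmsecv_mean)))
}
cat("Wrote fusion_report.csv, pc_scan_*.csv, evr_*.csv under results/\n")
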