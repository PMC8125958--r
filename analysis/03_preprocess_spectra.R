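#!/usr/bin/env Rscript
# Stage 3 — NIR spectral preprocessing.
#
# Savitzky-Golay smoothing (window 11, order 2) then SNV on every spectrum.
# Writes the preprocessed intensity matrix (one row per sample) to
# results/spectra_preprocessed.csv.

suppressPackageStartupMessages(library(ricefusion))

manifest <- read_manifest("results/cohort")
S <- read_manifest_spectra(manifest)
P <- preprocess_spectra(S, window = 11L, polyorder = 2L)

out <- cbind(data.frame(sample_id = manifest$sample_id),
             as.data.frame(P))
names(out)[-1] <- sprintf("wl_%.1f", attr(S, "wavelengths"))
write.csv(out, "results/spectra_preprocessed.csv", row.names = FALSE)
cat("Preprocessed", nrow(P), "spectra x", ncol(P), "points",
    "(each standardized to mean 0, sd 1)",
    "-> results/spectra_preprocessed.csv\n")
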