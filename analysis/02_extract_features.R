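#!/usr/bin/env Rscript
# Stage 2 — sensor-array image analysis.
#
# For every manifest sample: median-filter the before/after scans, segment the
# 15 dye spots, extract per-spot mean RGB over 15-px disks, difference them
# into the 45 delta components. Writes results/features_sensor.csv and a few
# gray difference images (the visualization of the normalized deltas).

suppressPackageStartupMessages(library(ricefusion))

manifest <- read_manifest("results/cohort")
features <- extract_manifest_features(manifest)
write.csv(features, "results/features_sensor.csv", row.names = FALSE)
cat("Extracted", ncol(features) - 1L, "color components for",
    nrow(features), "samples -> results/features_sensor.csv\n")

# difference images for the first sample of each storage month
dir.create("results/difference_images", showWarnings = FALSE)
first_rows <- match(unique(manifest$month), manifest$month)
for (i in first_rows) {
  v <- as.numeric(features[i, -1])
  attr(v, "normalized") <- FALSE
  img <- difference_image(normalize_deltas(v))
  png::writePNG(img / 255,
                sprintf("results/difference_images/month%02d.png",
                        manifest$month[i]))
}
cat("Wrote", length(first_rows), "difference images",
    "-> results/difference_images/\n")
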