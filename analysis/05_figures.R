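#!/usr/bin/env Rscript
# Stage 5 — figures.
#
# Visual summaries of the stage 1-4 outputs: the fatty-acid storage trend,
# each modality's explained-variance (covariance contribution) curve, and the
# RMSECV-vs-number-of-PCs scans behind the component-count choice.

suppressPackageStartupMessages({
  library(ricefusion)
  library(ggplot2)
})

dir.create("results/figures", showWarnings = FALSE)
manifest <- read_manifest("results/cohort")

p1 <- ggplot(manifest, aes(factor(month), fatty_acid)) +
  geom_boxplot(fill = "grey85") +
  labs(x = "Storage month", y = "Fatty acid (mg/100 g)",
       title = "Fatty acid rises over storage") +
  theme_minimal()
ggsave("results/figures/fatty_acid_trend.png", p1, width = 5, height = 3.2,
       dpi = 150)

for (mod in c("sensor", "nir")) {
  evr <- read.csv(sprintf("results/evr_%s.csv", mod))
  evr <- evr[1:min(10, nrow(evr)), ]
  p <- ggplot(evr, aes(pc, 100 * evr)) +
    geom_col(fill = "steelblue") +
    geom_line(aes(y = 100 * cumulative_evr), linewidth = 0.4) +
    geom_point(aes(y = 100 * cumulative_evr), size = 1) +
    labs(x = "Principal component", y = "Contribution rate (%)",
         title = sprintf("Variance explained (%s)", mod)) +
    theme_minimal()
  ggsave(sprintf("results/figures/evr_%s.png", mod), p,
         width = 5, height = 3.2, dpi = 150)

  scan <- read.csv(sprintf("results/pc_scan_%s.csv", mod))
  p2 <- ggplot(scan, aes(k, rmsecv_mean)) +
    geom_line() +
    geom_pointrange(aes(ymin = rmsecv_mean - rmsecv_sd,
                        ymax = rmsecv_mean + rmsecv_sd), size = 0.25) +
    labs(x = "Number of PCs", y = "Mean RMSECV (mg/100 g)",
         title = sprintf("PC-count scan (%s)", mod)) +
    theme_minimal()
  ggsave(sprintf("results/figures/pc_scan_%s.png", mod), p2,
         width = 5, height = 3.2, dpi = 150)
}
cat("Wrote figures under results/figures/\n")
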