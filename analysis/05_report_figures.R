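#!/usr/bin/env Rscript
# Figures: ROC curves for the seven feature-bank combinations and the
# distribution of two-cycle segment durations.

suppressPackageStartupMessages(library(gaitdep))

roc <- read.csv("results/roc_points.csv")
feat <- read.csv("results/features.csv", check.names = FALSE)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

pdf("results/figures/roc_curves.pdf", width = 6, height = 6)
combos <- unique(roc$combination)
cols <- seq_along(combos)
plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
     xlab = "False positive rate", ylab = "True positive rate",
     main = "ROC by feature-bank combination")
for (i in seq_along(combos)) {
  r <- roc[roc$combination == combos[i], ]
  lines(r$fpr, r$tpr, col = cols[i], lwd = 1.5)
}
legend("bottomright", legend = combos, col = cols, lwd = 1.5, cex = 0.7)
dev.off()

pdf("results/figures/segment_durations.pdf", width = 6, height = 4)
hist(feat$segment_duration_s, breaks = 20, col = "grey",
     xlab = "Two-cycle segment duration (s)",
     main = "Detected gait-segment durations")
dev.off()

cat("wrote results/figures/roc_curves.pdf and segment_durations.pdf\n")
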