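#!/usr/bin/env Rscript
# Inferential stage: case/control summary of the spatiotemporal features
# (group means, SDs, pooled t), PCA of the time- and frequency-domain banks
# at 95 % cumulative variance, stepwise forward logistic regression with
# odds ratios and Nagelkerke R2 per bank, and PC-feature Pearson
# correlation tables.

suppressPackageStartupMessages(library(gaitdep))

feat <- read.csv("results/features.csv", check.names = FALSE)
y <- feat$group
X <- as.matrix(feat[, -(1:3)])
blk <- c(rep("spatiotemporal", 10), rep("time", 300), rep("frequency", 825))

st <- X[, blk == "spatiotemporal"]
gt <- group_summary(st, y)
write.csv(gt, "results/spatiotemporal_group_table.csv", row.names = FALSE)
cat("spatiotemporal group differences (|t| > 2):\n")
print(gt[abs(gt$t) > 2, c("feature", "case_mean", "control_mean", "t", "p")],
      digits = 3)

for (b in c("spatiotemporal", "time", "frequency")) {
  Xb <- X[, blk == b]
  if (b == "spatiotemporal") {
    fit <- stepwise_logistic(Xb, y)
  } else {
    pca <- suppressWarnings(pca_reduce(Xb))
    cat(sprintf("%s: %d PCs reach 95%% cumulative variance\n",
                b, pca$n_retained))
    fit <- suppressWarnings(stepwise_logistic(retained_scores(pca), y))
    cm <- pc_feature_correlations(pca, Xb)
    write.csv(data.frame(component = rownames(cm), cm, check.names = FALSE),
              sprintf("results/pc_feature_correlations_%s.csv", b),
              row.names = FALSE)
  }
  cat(sprintf("%s: %d terms selected, Nagelkerke R2 = %.2f%%\n",
              b, nrow(fit$terms), 100 * fit$nagelkerke_r2))
  tab <- cbind(fit$terms, nagelkerke_r2 = rep(fit$nagelkerke_r2,
                                              nrow(fit$terms)))
  write.csv(tab, sprintf("results/logistic_%s.csv", b), row.names = FALSE)
}
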