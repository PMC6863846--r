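#!/usr/bin/env Rscript
# Per-cell richness, the sampling-effort regression, the study-area
# accumulation curve, the 1,000-draw bootstrap species-area null with
# quantile outlier classes, and the resampling t-tests of karst richness
# against the study area.
source("analysis/00_config.R")

res <- run_stage("richness", config)
cat(sprintf("bootstrap SAR slope z: mean %.3f (sd %.3f); expected species per 10 km cell: %.1f\n",
            mean(res$null$z), sd(res$null$z), mean(res$null$mean_curve_s10)))
cls <- table(factor(res$outliers$outlier_class, levels = c(-1, 1, 2)))
cat(sprintf("NBZ outlier classes: %d lower / %d non / %d upper\n",
            cls[1], cls[2], cls[3]))
for (nm in names(res$tests)) {
  t <- res$tests[[nm]]
  cat(sprintf("%s vs study area: observed mean richness %.1f, t = %.2f (df = %d), empirical p = %.3g\n",
              toupper(nm), t$observed, t$t, t$df, t$p_empirical))
}
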