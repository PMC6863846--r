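#!/usr/bin/env Rscript
# Range sizes, weighted endemism (with the 2,000-draw randomization null
# in the NBZ extent), small-range-species statistics on both range bases,
# extent endemics and the log-log endemics-vs-area table.
source("analysis/00_config.R")

res <- run_stage("endemism", config)
sr <- res$small_range
cat("small-range species proportions:\n")
print(sr, row.names = FALSE)
cat(sprintf("extent endemics: %d (NBZ), %d (BZ5)\n",
            length(res$endemics$nbz), length(res$endemics$bz5)))
sig <- table(res$we$nbz$significance)
cat("NBZ weighted-endemism significance:",
    paste(names(sig), sig, collapse = ", "), "\n")
for (nm in names(res$tests)) {
  t <- res$tests[[nm]]
  cat(sprintf("small-range proportion, %s vs study: observed %.3f, t = %.2f, empirical p = %.3g\n",
              toupper(nm), t$observed, t$t, t$p_empirical))
}
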