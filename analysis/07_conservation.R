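#!/usr/bin/env Rscript
# Cross-tabulate the species lists of each extent against IUCN categories
# and build the extent summary table (area, records, taxa, endemics,
# maximum cell richness, with percentages of the country total).
source("analysis/00_config.R")

res <- run_stage("conservation", config)
cat("IUCN cross-tabulation:\n")
print(as.data.frame(res$crosstab), row.names = FALSE)
cat("\nextent summary:\n")
print(as.data.frame(res$summary), row.names = FALSE)
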