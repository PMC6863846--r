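#!/usr/bin/env Rscript
# Collate every stage's outputs into results/pipeline/report.{json,txt}.
source("analysis/00_config.R")

res <- run_stage("report", config)
cat(readLines(file.path(config$out_dir, "report.txt")), sep = "\n")
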