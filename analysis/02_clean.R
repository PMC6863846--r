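#!/usr/bin/env Rscript
# Coordinate cleaning and name reconciliation against the stricter
# backbone, with the per-step loss report and backbone-congruence table.
source("analysis/00_config.R")

res <- run_stage("clean", config)
cat(sprintf("cleaning kept %d of %d records (%.1f%% lost)\n",
            attr(res$clean_report, "retained"),
            attr(res$clean_report, "input"),
            attr(res$clean_report, "pct_lost")))
cong <- res$congruence
cat(sprintf("backbone congruence: %.1f%% shared, %.1f%% synonymous, %.1f%% not found\n",
            cong$pct[cong$status == "shared"],
            cong$pct[cong$status == "synonymous"],
            cong$pct[cong$status == "not_found"]))
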