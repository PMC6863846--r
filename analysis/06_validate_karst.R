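#!/usr/bin/env Rscript
# Validate the karst map against collection-label metadata: keyword
# filtering of habitat notes, the 1 km proximity rule for cave terms, the
# polygon rule for doline terms, and overlay congruence with candidate
# undocumented outcrops.
source("analysis/00_config.R")

res <- run_stage("validate_karst", config)
print(res$proximity$report, row.names = FALSE)
cat(sprintf("retained %d keyword records; %.1f%% inside mapped karst, %.1f%% within 5 km\n",
            res$congruence$n, 100 * res$congruence$fraction_inside,
            100 * res$congruence$fraction_within_threshold))
cat(sprintf("%d candidate undocumented outcrop record(s)\n",
            nrow(res$congruence$candidates)))
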