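#!/usr/bin/env Rscript
# Buffer the karst extent by 5 km (BZ5), define the study-area bounding
# box, and assign every cleaned record to 50 km and 10 km equal-area cells.
source("analysis/00_config.R")

res <- run_stage("grid", config)
cat(sprintf("extents: NBZ %.0f km2, BZ5 %.0f km2, study area %.0f km2\n",
            res$nbz$area_km2, res$bz5$area_km2, res$study$area_km2))
cat(sprintf("records inside NBZ: %d, BZ5: %d, study area: %d\n",
            sum(res$records$inside_nbz), sum(res$records$inside_bz5),
            sum(res$records$inside_study)))
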