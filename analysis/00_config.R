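# Shared settings for the numbered analysis scripts. Each script sources
# this file, runs one pipeline stage, and narrates what it found; all
# tables land under results/pipeline/.
suppressPackageStartupMessages(library(karstflora))

analysis_seed <- as.integer(Sys.getenv("KARSTFLORA_SEED", "2024"))
config <- pipeline_config(out_dir = "results/pipeline", seed = analysis_seed)
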