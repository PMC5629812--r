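# Shared settings for the analysis scripts. Each script can be run on its
# own from the repository root after `R CMD INSTALL .`; outputs accumulate
# under results/.
library(landconnect)
SEED <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)
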