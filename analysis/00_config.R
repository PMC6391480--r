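# Shared settings for the analysis scripts. Sourced by 01..07.
# All outputs go under results/; raw synthetic inputs under results/data/.

library(tadenrich)

SEED <- 1
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

# Study-shaped generator configuration: ~1,200 TADs over 8 chromosomes,
# wide-spread inter-TAD complement, 10% GR-bearing TADs, 600 bp features.
STUDY_CFG <- simulation_config(seed = SEED)

msg <- function(...) cat(sprintf(...), "\n")
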