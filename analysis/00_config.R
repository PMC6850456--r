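# Shared settings for the analysis scripts. Every script can be run on its
# own; stages re-derive what they need deterministically from this seed.
suppressPackageStartupMessages(library(specshift))

SEED <- 2017L
DATA_DIR <- "results/data"
OUT_DIR <- "results"
SIM <- sim_config(seed = SEED)      # study-scale defaults (~700 species)
N_DRAWS <- 10000L

dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

load_pair <- function() {
  list(a = read_snapshot(file.path(DATA_DIR, "snapshot_2007.csv"),
                         label = "2007"),
       b = read_snapshot(file.path(DATA_DIR, "snapshot_2017.csv"),
                         label = "2017"),
       map = read_curation_map(file.path(DATA_DIR, "curation_map.csv")))
}
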