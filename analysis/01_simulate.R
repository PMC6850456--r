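#!/usr/bin/env Rscript
# Stage 1: simulate a decade of curation on a monographic specimen
# database - paired snapshots, ground-truth change log, curation map.
source("analysis/00_config.R")

pair <- generate_pair(SIM)

write_snapshot(pair$a, file.path(DATA_DIR, "snapshot_2007.csv"))
write_snapshot(pair$b, file.path(DATA_DIR, "snapshot_2017.csv"))
write_curation_map(pair$map, file.path(DATA_DIR, "curation_map.csv"))
write_change_log(pair$truth, file.path(DATA_DIR, "truth_log.csv"))

sa <- snapshot_summary(pair$a)
sb <- snapshot_summary(pair$b)
message(sprintf("2007 snapshot: %d records, %d species, %.0f%% georeferenced",
                sa$n_records, sa$n_species, 100 * sa$frac_georeferenced))
message(sprintf("2017 snapshot: %d records, %d species, %.0f%% georeferenced",
                sb$n_records, sb$n_species, 100 * sb$frac_georeferenced))
message(sprintf("specimen growth over the decade: %.0f%%",
                100 * (sb$n_records - sa$n_records) / sa$n_records))
message(sprintf("ground truth: %d change events, %d curation-map entries",
                nrow(pair$truth), nrow(pair$map)))
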