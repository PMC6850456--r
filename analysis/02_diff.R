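#!/usr/bin/env Rscript
# Stage 2: match records across the two snapshots and classify every
# difference into the nine change classes.
source("analysis/00_config.R")

pair <- load_pair()
events <- diff_snapshots(pair$a, pair$b, map = pair$map)
write_change_log(events, file.path(OUT_DIR, "change_log.csv"))

counts <- tabulate_changes(events)
readr::write_csv(counts, file.path(OUT_DIR, "change_counts.csv"))
message("change events by class:")
for (i in seq_len(nrow(counts)))
  message(sprintf("  %-22s %6d", counts$minor_class[i], counts$n[i]))

adds <- additions_by_collection_year(events, SIM$cutoff_year)
readr::write_csv(adds, file.path(OUT_DIR, "additions_summary.csv"))
message(sprintf(
  "%.0f%% of the %d dated additions were collected in or before %d",
  100 * adds$fraction_at_or_before, adds$n_known_year, SIM$cutoff_year))

persisting <- length(match_records(pair$a, pair$b)$persisting)
changed <- length(unique(events$record_id[
  events$minor_class != "new_specimen"]))
message(sprintf("%.0f%% of the %d persisting records changed",
                100 * changed / persisting, persisting))
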