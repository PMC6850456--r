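#!/usr/bin/env Rscript
# Stage 3: preliminary Criterion B assessments (EOO-only) per species per
# snapshot, and gridded specimen/species counts.
source("analysis/00_config.R")

pair <- load_pair()
for (yr in c("a", "b")) {
  s <- pair[[yr]]
  ass <- assess_snapshot(s)
  readr::write_csv(ass, file.path(OUT_DIR,
                                  paste0("assessments_", s$label, ".csv")))
  tab <- table(factor(ass$category,
                      levels = c("CR", "EN", "VU", "NT", "LC", "DD")))
  message(s$label, " categories: ",
          paste(names(tab), tab, sep = "=", collapse = " "))
  g <- grid_counts(s)
  readr::write_csv(g, file.path(OUT_DIR,
                                paste0("grid_counts_", s$label, ".csv")))
}
d <- grid_diff(
  grid_counts(pair$a), grid_counts(pair$b))
readr::write_csv(d, file.path(OUT_DIR, "grid_difference.csv"))
message(sprintf("grid cells occupied: %d (2007) -> %d (2017)",
                sum(d$specimen_count_a > 0), sum(d$specimen_count_b > 0)))
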