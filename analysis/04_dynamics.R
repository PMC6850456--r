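#!/usr/bin/env Rscript
# Stage 4: category dynamics between the snapshots - transition matrix on
# harmonized names, per-category turnover, EOO change table, and Bayesian
# comparisons of category counts and the threatened proportion.
source("analysis/00_config.R")

pair <- load_pair()
events <- diff_snapshots(pair$a, pair$b, map = pair$map)

ass_a <- assess_snapshot(pair$a)
ass_b <- assess_snapshot(pair$b)
harm <- assess_snapshot(harmonize_names(pair$a, events))

m <- transition_matrix(harm, ass_b)
readr::write_csv(tibble::as_tibble(as.data.frame(m)),
                 file.path(OUT_DIR, "transition_matrix.csv"))

turn <- category_turnover(harm, ass_b)
readr::write_csv(turn, file.path(OUT_DIR, "category_turnover.csv"))
message("per-category Sorensen turnover:")
for (i in seq_len(nrow(turn)))
  message(sprintf("  %s: %.2f (%d -> %d species)", turn$category[i],
                  turn$sorensen[i], turn$n_earlier[i], turn$n_later[i]))

changes <- eoo_change_table(harm, ass_b)
readr::write_csv(changes, file.path(OUT_DIR, "eoo_changes.csv"))
s <- eoo_change_summary(changes)
readr::write_csv(s, file.path(OUT_DIR, "eoo_change_summary.csv"))
message(sprintf(
  "of %d species matched across years: EOO up %.0f%%, down %.0f%%; %.0f%% became less threatened, %.0f%% more threatened",
  s$n_matched, s$pct_eoo_increased, s$pct_eoo_decreased,
  s$pct_less_threatened, s$pct_more_threatened))

cmp <- compare_category_counts(ass_a, ass_b, n_draws = N_DRAWS,
                               seed = SEED + 1L)
readr::write_csv(cmp$categories, file.path(OUT_DIR,
                                           "category_posteriors.csv"))
readr::write_csv(cmp$threatened, file.path(OUT_DIR,
                                           "threatened_posterior.csv"))
sig <- cmp$categories$parameter[cmp$categories$significant]
message("significant category-count shifts: ",
        if (length(sig)) paste(sig, collapse = ", ") else "none")
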