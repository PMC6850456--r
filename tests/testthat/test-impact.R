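test_that("corrections expand into their two species-side tasks", {
  a <- toy_snapshot(c("1", "2"), c("Genus alpha", "Genus beta"),
                    lat = c(1, 2), lon = c(1, 2))
  b <- toy_snapshot(c("1", "2"), c("Genus beta", "Genus beta"),
                    lat = c(1, 2), lon = c(1, 2))
  ev <- diff_snapshots(a, b)
  expanded <- expand_corrections(ev)
  expect_setequal(expanded$minor_class, c("correction_out", "correction_in"))
  expect_identical(nrow(expanded), 2L)
  # gaining species absent from 2007 -> out task only
  only_out <- expand_corrections(ev, species_2007 = "Genus alpha")
  expect_identical(only_out$minor_class, "correction_out")
  # no corrections -> identity
  none <- diff_snapshots(a, a)
  expect_identical(expand_corrections(none), none)
})

test_that("hypothetical EOO applies exactly one specimen change", {
  occ <- list("Genus alpha" = tibble::tibble(
    record_id = as.character(1:4),
    latitude = c(0, 0, 1, 1), longitude = c(0, 1, 1, 0)))
  base <- compute_eoo(occ[[1]]$latitude, occ[[1]]$longitude)

  # out-task removing a hull vertex of the square leaves the triangle:
  # on this near-planar square the loss is half the area
  hyp_out <- hypothetical_eoo(list(species = "Genus alpha",
                                   direction = "out", record_id = "1"),
                              occ)
  expect_equal(hyp_out / base, 0.5, tolerance = 0.01)

  # in-task with a point inside the hull changes nothing
  hyp_in <- hypothetical_eoo(list(species = "Genus alpha",
                                  direction = "in", record_id = "9",
                                  point_2017 = c(0.5, 0.5)), occ)
  expect_equal(hyp_in, base)

  # substitute replaces exactly one point
  hyp_sub <- hypothetical_eoo(list(species = "Genus alpha",
                                   direction = "substitute",
                                   record_id = "1",
                                   point_2017 = c(0, 0)), occ)
  expect_equal(hyp_sub, base)

  expect_error(hypothetical_eoo(list(species = "Genus alpha",
                                     direction = "out",
                                     record_id = "99"), occ),
               "not in the 2007 occurrence set")
})

test_that("attribution excludes nomenclature and applies taxonomic precedence", {
  a <- toy_snapshot(as.character(1:3), rep("Genus alpha", 3),
                    lat = c(0, 0, 1), lon = c(0, 1, 0))
  b <- toy_snapshot(as.character(1:3), rep("Genus nova", 3),
                    lat = c(0, 0, 1), lon = c(0, 1, 0))
  map <- curation_map("Genus alpha", "Genus nova", "nomenclatural")
  ev <- diff_snapshots(a, b, map = map)
  expect_identical(nrow(attribute_all(ev, a, b)), 0L)

  # name + coordinate change on one record -> one taxonomic impact only
  a2 <- snapshot(tibble::tibble(
    record_id = as.character(1:6),
    scientific_name = c(rep("Genus alpha", 4), "Genus beta", "Genus beta"),
    latitude = c(0, 0, 1, 1, 5, 6), longitude = c(0, 1, 1, 0, 5, 6)))
  b2 <- snapshot(tibble::tibble(
    record_id = as.character(1:6),
    scientific_name = c(rep("Genus alpha", 3), "Genus beta", "Genus beta",
                        "Genus beta"),
    latitude = c(0, 0, 1, 7, 5, 6), longitude = c(0, 1, 1, 7, 5, 6)))
  ev2 <- diff_snapshots(a2, b2)
  expect_setequal(ev2$minor_class[ev2$record_id == "4"],
                  c("correction", "corrected_coordinates"))
  imp <- attribute_all(ev2, a2, b2)
  rec4 <- imp[imp$record_id == "4", ]
  expect_identical(nrow(rec4), 2L)  # correction duality, no geo task
  expect_setequal(rec4$minor_class, c("correction_out", "correction_in"))
  # losing species shrinks, gaining species grows
  out <- rec4[rec4$minor_class == "correction_out", ]
  expect_lte(out$delta_eoo, 0)
  expect_identical(out$species, "Genus alpha")
  inn <- rec4[rec4$minor_class == "correction_in", ]
  expect_gte(inn$delta_eoo, 0)
  expect_identical(inn$species, "Genus beta")
  # the gaining species' hypothetical set uses the 2017 coordinates
  expect_equal(inn$hypothetical_eoo,
               compute_eoo(c(5, 6, 7), c(5, 6, 7)), tolerance = 1e-9)
})

test_that("sign constraints hold for in- and out-tasks on simulated data", {
  pair <- generate_pair(sim_config(n_species = 60, seed = 5))
  ev <- diff_snapshots(pair$a, pair$b, map = pair$map)
  imp <- attribute_all(ev, pair$a, pair$b)
  expect_true(all(imp$delta_eoo[imp$direction == "in"] >= -1e-9))
  expect_true(all(imp$delta_eoo[imp$direction == "out"] <= 1e-9))
  # each non-nomenclatural event yields at most 2 impact rows; exactly 2
  # only for corrections
  per_record <- table(imp$record_id)
  expect_true(all(per_record <= 2))
  two <- names(per_record)[per_record == 2]
  expect_true(all(imp$minor_class[imp$record_id %in% two] %in%
                    c("correction_in", "correction_out")))
  # skip mode drops data-deficient rows instead of zeroing them
  imp_skip <- attribute_all(ev, pair$a, pair$b, dd_mode = "skip")
  expect_false(any(imp_skip$dd_involved))
})

test_that("impact summaries report per-class means and standard errors", {
  imp <- tibble::tibble(
    record_id = as.character(1:5),
    minor_class = c("new_specimen", "new_specimen", "new_specimen",
                    "correction_out", "split"),
    species = "s", direction = c("in", "in", "in", "out", "out"),
    eoo_2007 = 0, hypothetical_eoo = 0,
    delta_eoo = c(2, 4, 6, -3, 0), dd_involved = FALSE)
  s <- summarize_impacts(imp)
  ns <- s[s$minor_class == "new_specimen", ]
  expect_identical(ns$n, 3L)
  expect_equal(ns$mean_delta_eoo, 4)
  expect_equal(ns$se_delta_eoo, sd(c(2, 4, 6)) / sqrt(3))
  # single impact per class: SE undefined
  expect_true(is.na(s$se_delta_eoo[s$minor_class == "split"]))
  # all-zero deltas
  z <- summarize_impacts(dplyr::mutate(imp, delta_eoo = 0))
  expect_true(all(z$mean_delta_eoo == 0))
})

test_that("change-profile comparison flags types exclusive to changed species", {
  set.seed(8)
  imp <- tibble::tibble(
    record_id = as.character(1:400),
    minor_class = c(rep("new_specimen", 200), rep("new_coordinates", 200)),
    species = c(rep("stable sp", 200), rep("changed sp", 200)),
    direction = "in", eoo_2007 = 0, hypothetical_eoo = 0, delta_eoo = 0,
    dd_involved = FALSE)
  res <- compare_change_profiles(imp, changed_species = "changed sp",
                                 n_draws = 5000, seed = 9)
  nc <- res[res$parameter == "new_coordinates", ]
  expect_true(nc$significant)
  expect_gt(nc$mean_difference, 0)

  # identical profiles -> nothing significant
  imp2 <- dplyr::mutate(imp, minor_class = rep(c("new_specimen",
                                                 "new_coordinates"), 200))
  res2 <- compare_change_profiles(imp2, changed_species = "changed sp",
                                  n_draws = 5000, seed = 10)
  expect_false(any(res2$significant))

  # seed-fixed rerun is identical; universe filter drops foreign species
  res3 <- compare_change_profiles(imp, changed_species = "changed sp",
                                  n_draws = 5000, seed = 9)
  expect_identical(res, res3)
  res4 <- compare_change_profiles(imp, changed_species = "changed sp",
                                  species_universe = "changed sp",
                                  n_draws = 100, seed = 9)
  expect_identical(unique(res4$n_stable), 0L)
})
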