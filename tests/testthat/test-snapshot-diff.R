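test_that("record matching partitions the union of identifiers", {
  a <- toy_snapshot(c("1", "2"), c("Genus alpha", "Genus beta"))
  b <- toy_snapshot(c("2", "3"), c("Genus beta", "Genus gamma"))
  m <- match_records(a, b)
  expect_identical(m$additions, "3")
  expect_identical(m$persisting, "2")
  expect_identical(m$disappeared, "1")

  expect_identical(match_records(a, a)$additions, character(0))
  expect_identical(match_records(a, a)$persisting, c("1", "2"))

  empty <- snapshot(tibble::tibble(record_id = character(),
                                   scientific_name = character()))
  expect_identical(match_records(empty, b)$additions, b$records$record_id)

  # every id in exactly one of the three sets
  ids <- union(a$records$record_id, b$records$record_id)
  expect_setequal(c(m$additions, m$persisting, m$disappeared), ids)
  expect_identical(anyDuplicated(c(m$additions, m$persisting,
                                   m$disappeared)), 0L)
})

test_that("rank transitions outrank the curation map and name heuristics", {
  a <- toy_snapshot(c("1", "2"), c("Genus", "Genus alpha"))
  b <- toy_snapshot(c("1", "2"), c("Genus alphaA", "Genus"))
  ctx <- list(a = a, b = b)
  map <- curation_map("Genus", "Genus alphaA", "nomenclatural")
  expect_identical(
    classify_name_change(list(scientific_name = "Genus", rank = "genus"),
                         list(scientific_name = "Genus alphaA",
                              rank = "species"), map, ctx),
    "upgraded_to_species")
  expect_identical(
    classify_name_change(list(scientific_name = "Genus alpha",
                              rank = "species"),
                         list(scientific_name = "Genus", rank = "genus"),
                         NULL, ctx),
    "downgraded_to_genus")
})

test_that("curation map entries drive nomenclatural / lumped / split classes", {
  a <- toy_snapshot(as.character(1:3),
                    c("Genus alpha", "Genus alpha", "Genus beta"))
  b <- toy_snapshot(as.character(1:3),
                    c("Genus nova", "Genus nova", "Genus beta"))
  map <- curation_map("Genus alpha", "Genus nova", "nomenclatural")
  ev <- diff_snapshots(a, b, map = map)
  expect_identical(unique(ev$minor_class), "nomenclatural")
  expect_identical(nrow(ev), 2L)

  map2 <- curation_map("Genus alpha", "Genus beta", "lump")
  b2 <- toy_snapshot(as.character(1:3), rep("Genus beta", 3))
  ev2 <- diff_snapshots(a, b2, map = map2)
  expect_identical(unique(ev2$minor_class), "lumped")
})

test_that("the movement heuristic separates corrections, lumps and splits", {
  # 12 records of alpha; 5 move to a name absent earlier -> split each
  a <- toy_snapshot(as.character(1:12), rep("Genus alpha", 12))
  names_b <- c(rep("Genus nova", 5), rep("Genus alpha", 7))
  b <- toy_snapshot(as.character(1:12), names_b)
  ev <- diff_snapshots(a, b)
  expect_identical(nrow(ev), 5L)
  expect_identical(unique(ev$minor_class), "split")

  # move to a name already present earlier -> correction
  a2 <- toy_snapshot(c("1", "2"), c("Genus alpha", "Genus beta"))
  b2 <- toy_snapshot(c("1", "2"), c("Genus beta", "Genus beta"))
  ev2 <- diff_snapshots(a2, b2)
  expect_identical(ev2$minor_class, "correction")

  # whole species moves to a brand-new name, old name gone -> lumped
  # (low confidence: indistinguishable from mass correction without a map)
  a3 <- toy_snapshot(c("1", "2"), rep("Genus alpha", 2))
  b3 <- toy_snapshot(c("1", "2"), rep("Genus nova", 2))
  ev3 <- diff_snapshots(a3, b3)
  expect_identical(unique(ev3$minor_class), "lumped")
  expect_true(all(ev3$low_confidence))
})

test_that("georeference changes classify against the tolerance", {
  old <- list(latitude = NA_real_, longitude = NA_real_)
  new <- list(latitude = -10.5, longitude = -48.2)
  expect_identical(classify_geo_change(old, new), "new_coordinates")
  expect_identical(classify_geo_change(new, new), NA_character_)
  moved <- list(latitude = -10.2, longitude = -48.2)
  expect_identical(classify_geo_change(new, moved, tolerance = 1 / 120),
                   "corrected_coordinates")
  # within tolerance: unchanged
  near <- list(latitude = -10.5 + 1 / 300, longitude = -48.2)
  expect_identical(classify_geo_change(new, near, tolerance = 1 / 120),
                   NA_character_)
  expect_identical(classify_geo_change(new, old), "coordinate_loss")
})

test_that("diffing identical snapshots yields no events", {
  s <- toy_snapshot(as.character(1:3), rep("Genus alpha", 3),
                    lat = c(1, 2, 3), lon = c(1, 2, 3))
  ev <- diff_snapshots(s, s)
  expect_identical(nrow(ev), 0L)
})

test_that("a record can carry one name event and one geography event", {
  a <- toy_snapshot(c("1", "2"), c("Genus alpha", "Genus beta"),
                    lat = c(1, 2), lon = c(1, 2))
  b <- snapshot(tibble::tibble(
    record_id = c("1", "2", "3"),
    scientific_name = c("Genus beta", "Genus beta", "Genus beta"),
    latitude = c(5, 2, 3), longitude = c(5, 2, 3),
    collection_year = c(NA, NA, 2001L)))
  ev <- diff_snapshots(a, b)
  # addition + name change + coordinate change = 3 events
  expect_identical(nrow(ev), 3L)
  expect_setequal(ev$minor_class,
                  c("new_specimen", "correction", "corrected_coordinates"))
  expect_identical(sum(ev$record_id == "1"), 2L)
  counts <- tabulate_changes(ev)
  expect_identical(sum(counts$n), nrow(ev))
  expect_identical(counts$n[counts$minor_class == "new_specimen"], 1L)
})

test_that("tabulation covers all nine classes and sums to the event count", {
  empty <- diff_snapshots(toy_snapshot("1", "Genus alpha"),
                          toy_snapshot("1", "Genus alpha"))
  tab <- tabulate_changes(empty)
  expect_identical(nrow(tab), 9L)
  expect_true(all(tab$n == 0L))
})

test_that("additions are summarised by collection year against a cutoff", {
  a <- snapshot(tibble::tibble(record_id = "0",
                               scientific_name = "Genus alpha"))
  yrs <- c(rep(2000L, 79), rep(2010L, 21))
  b <- snapshot(tibble::tibble(
    record_id = as.character(0:100),
    scientific_name = "Genus alpha",
    collection_year = c(NA_integer_, yrs)))
  ev <- diff_snapshots(a, b)
  s <- additions_by_collection_year(ev, 2007)
  expect_identical(s$n_additions, 100L)
  expect_identical(s$n_known_year, 100L)
  expect_equal(s$fraction_at_or_before, 0.79)

  # all after cutoff -> 0; no known years -> undefined
  expect_equal(additions_by_collection_year(ev, 1990)$fraction_at_or_before, 0)
  b2 <- snapshot(tibble::tibble(record_id = c("0", "1"),
                                scientific_name = "Genus alpha"))
  ev2 <- diff_snapshots(a, b2)
  expect_true(is.na(additions_by_collection_year(ev2, 2007)$fraction_at_or_before))
})

test_that("swapping snapshots maps additions to disappearances and coordinate gains to losses", {
  a <- toy_snapshot(c("1", "2"), c("Genus alpha", "Genus beta"),
                    lat = c(NA, 2), lon = c(NA, 2))
  b <- toy_snapshot(c("2", "3"), c("Genus beta", "Genus gamma"),
                    lat = c(NA, 3), lon = c(NA, 3))
  fwd <- diff_snapshots(a, b)
  rev <- diff_snapshots(b, a)
  expect_setequal(attr(fwd, "disappeared"),
                  fwd_add <- rev$record_id[rev$minor_class == "new_specimen"])
  expect_identical(attr(fwd, "anomalies")$record_id, "2")
  expect_identical(rev$record_id[rev$minor_class == "new_coordinates"], "2")
})
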