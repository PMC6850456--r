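make_assess <- function(species, category, eoo = NULL) {
  if (is.null(eoo))
    eoo <- ifelse(category == "DD", NA_real_,
                  c(CR = 50, EN = 1000, VU = 10000, NT = 25000,
                    LC = 50000)[category])
  tibble::tibble(species = species, category = category, eoo_km2 = eoo)
}

test_that("transition matrices cross-tabulate matched species with absent margins", {
  a <- make_assess(c("s1", "s2", "s3"), c("LC", "DD", "VU"))
  b <- make_assess(c("s1", "s2", "s4"), c("LC", "EN", "CR"))
  m <- transition_matrix(a, b)
  expect_identical(m["LC", "LC"], 1L)
  expect_identical(m["DD", "EN"], 1L)
  expect_identical(m["VU", "absent"], 1L)
  expect_identical(m["absent", "CR"], 1L)
  expect_identical(sum(m), 4L)  # union of species
  # marginals equal per-snapshot category counts
  expect_equal(unname(rowSums(m)[c("LC", "DD", "VU")]), rep(1, 3))
  expect_identical(sum(m[, "absent"]), 1L)

  # identical assessments -> diagonal
  d <- transition_matrix(a, a)
  expect_identical(sum(d) - sum(diag(d)), 0L)
})

test_that("Sorensen dissimilarity satisfies its identities", {
  expect_identical(sorensen_dissimilarity(c("x", "y"), c("x", "y")), 0)
  expect_identical(sorensen_dissimilarity(c("x"), c("y")), 1)
  expect_equal(sorensen_dissimilarity(c("X", "Y"), c("Y", "Z")), 0.5)
  # symmetry and the 1 - 2a/(|A|+|B|) identity
  set.seed(11)
  pool <- paste0("sp", 1:20)
  for (i in 1:25) {
    A <- sample(pool, sample(0:10, 1))
    B <- sample(pool, sample(0:10, 1))
    d1 <- as.numeric(sorensen_dissimilarity(A, B))
    d2 <- as.numeric(sorensen_dissimilarity(B, A))
    expect_equal(d1, d2)
    if (length(A) + length(B) > 0) {
      a <- length(intersect(A, B))
      expect_equal(d1, 1 - 2 * a / (length(A) + length(B)))
    }
  }
  both_empty <- sorensen_dissimilarity(character(), character())
  expect_identical(as.numeric(both_empty), 0)
  expect_true(attr(both_empty, "both_empty"))
})

test_that("Sorensen agrees with the community-ecology reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  pool <- paste0("sp", 1:30)
  for (i in 1:10) {
    A <- sample(pool, sample(1:20, 1))
    B <- sample(pool, sample(1:20, 1))
    comm <- rbind(as.integer(pool %in% A), as.integer(pool %in% B))
    ref <- as.numeric(vegan::vegdist(comm, method = "bray"))
    expect_equal(as.numeric(sorensen_dissimilarity(A, B)), ref)
  }
})

test_that("per-category turnover reflects set replacement", {
  a <- make_assess(c("s1", "s2", "s3", "s4"), c("VU", "VU", "LC", "CR"))
  same <- category_turnover(a, a)
  expect_true(all(same$sorensen == 0))
  b <- make_assess(c("s1", "s2", "s3", "s4"), c("VU", "LC", "LC", "CR"))
  t2 <- category_turnover(a, b)
  # VU: {s1,s2} vs {s1}: a=1,b=1,c=0 -> 1/3
  expect_equal(t2$sorensen[t2$category == "VU"], 1 / 3)
  # complete replacement -> 1
  c2 <- make_assess(c("s9"), "CR")
  t3 <- category_turnover(a, c2)
  expect_equal(t3$sorensen[t3$category == "CR"], 1)
})

test_that("name harmonization rewrites names, not coordinates", {
  a <- toy_snapshot(as.character(1:3),
                    c("Genus alpha", "Genus alpha", "Genus beta"),
                    lat = c(1, 2, 3), lon = c(1, 2, 3))
  b <- toy_snapshot(as.character(1:3),
                    c("Genus nova", "Genus nova", "Genus beta"),
                    lat = c(1, 2, 3), lon = c(1, 2, 3))
  ev <- diff_snapshots(a, b,
                       map = curation_map("Genus alpha", "Genus nova",
                                          "nomenclatural"))
  h <- harmonize_names(a, ev)
  expect_identical(h$records$scientific_name,
                   c("Genus nova", "Genus nova", "Genus beta"))
  expect_identical(h$records$latitude, a$records$latitude)

  # no name events -> identity
  h2 <- harmonize_names(a, diff_snapshots(a, a))
  expect_identical(h2$records, a$records)

  # simulator oracle: harmonized names equal 2017 names for persisting ids
  pair <- generate_pair(sim_config(n_species = 40, seed = 77))
  ev3 <- diff_snapshots(pair$a, pair$b, map = pair$map)
  h3 <- harmonize_names(pair$a, ev3)
  later <- pair$b$records$scientific_name[
    match(h3$records$record_id, pair$b$records$record_id)]
  expect_identical(h3$records$scientific_name, later)
})

test_that("EOO change tables order threat transitions and partition species", {
  a <- make_assess(paste0("s", 1:6), c("VU", "LC", "DD", "EN", "DD", "LC"),
                   eoo = c(10000, 50000, NA, 1000, NA, 60000))
  b <- make_assess(paste0("s", 1:6), c("LC", "VU", "EN", "EN", "DD", "LC"),
                   eoo = c(40000, 15000, 2000, 1000, NA, 60000))
  tab <- eoo_change_table(a, b)
  expect_identical(tab$threat_direction[tab$species == "s1"],
                   "less_threatened")
  expect_identical(tab$threat_direction[tab$species == "s2"],
                   "more_threatened")
  expect_identical(tab$threat_direction[tab$species == "s3"], "from_DD")
  expect_identical(tab$threat_direction[tab$species == "s4"], "unchanged")
  expect_identical(tab$threat_direction[tab$species == "s5"], "unchanged")
  # the five threat directions partition the matched species
  expect_identical(nrow(tab), 6L)
  expect_true(all(tab$threat_direction %in%
                    c("less_threatened", "more_threatened", "unchanged",
                      "from_DD", "to_DD")))
  s <- eoo_change_summary(tab)
  expect_equal(s$pct_less_threatened, 100 / 6)
  expect_equal(s$pct_more_threatened, 100 / 6)
  expect_equal(s$pct_dd_to_threatened, 100 / 6)  # s3 -> EN
  expect_equal(s$pct_eoo_increased +
                 s$pct_eoo_decreased + s$pct_eoo_unchanged, 100)
})

test_that("category-count comparison flags only real shifts", {
  a <- make_assess(paste0("s", 1:30), rep(c("LC", "VU", "DD"), each = 10))
  cmp <- compare_category_counts(a, a, n_draws = 4000, seed = 1)
  expect_false(any(cmp$categories$significant))
  expect_false(cmp$threatened$significant)

  # CR: 100 vs 0 of 100 -> difference significant and negative,
  # matching the Beta(101, 1) vs Beta(1, 101) quantile oracle
  a2 <- make_assess(paste0("s", 1:100), rep("CR", 100))
  b2 <- make_assess(paste0("s", 1:100), rep("LC", 100))
  cmp2 <- compare_category_counts(a2, b2, n_draws = 10000, seed = 2)
  cr <- cmp2$categories[cmp2$categories$parameter == "CR", ]
  expect_true(cr$significant)
  expect_lt(cr$mean_difference, 0)
  oracle_hi <- qbeta(0.999, 1, 101) - qbeta(0.001, 101, 1)
  expect_lt(cr$ci_high, oracle_hi)

  # determinism under a fixed seed
  cmp3 <- compare_category_counts(a2, b2, n_draws = 10000, seed = 2)
  expect_identical(cmp2$categories, cmp3$categories)
})
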