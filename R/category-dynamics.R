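#' Category transition matrix between two assessments
#'
#' Cross-tabulates species by earlier and later preliminary category. An
#' `absent` pseudo-category on each margin holds species present in only
#' one snapshot. Species are matched by name, so the earlier assessment
#' should be computed on a name-harmonized snapshot (see
#' [harmonize_names()]) when taxonomy moved between years.
#'
#' @param assess_a,assess_b Assessment tables from [assess_snapshot()] for
#'   the earlier and later snapshot.
#' @return A 7x7 integer matrix (rows = earlier, columns = later) over
#'   CR, EN, VU, NT, LC, DD and `absent`.
#' @export
transition_matrix <- function(assess_a, assess_b) {
  levels <- c(.categories, "absent")
  all_sp <- union(assess_a$species, assess_b$species)
  cat_a <- assess_a$category[match(all_sp, assess_a$species)]
  cat_b <- assess_b$category[match(all_sp, assess_b$species)]
  cat_a[is.na(cat_a)] <- "absent"
  cat_b[is.na(cat_b)] <- "absent"
  m <- table(factor(cat_a, levels = levels), factor(cat_b, levels = levels))
  m <- unclass(m)
  dimnames(m) <- list(earlier = levels, later = levels)
  m
}

#' Sorensen dissimilarity of two species sets
#'
#' `(b + c) / (2a + b + c)` with `a` shared members and `b`, `c` unique to
#' each set: 0 for identical sets, 1 for disjoint non-empty sets. Two empty
#' sets give 0 by convention, flagged with attribute `both_empty`.
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @return Dissimilarity in `[0, 1]`.
#' @export
sorensen_dissimilarity <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  if (a + b + cc == 0)
    return(structure(0, both_empty = TRUE))
  (b + cc) / (2 * a + b + cc)
}

#' Per-category species turnover between two assessments
#'
#' For each real category, the Sorensen dissimilarity between the sets of
#' species assigned to it in the earlier and the later assessment.
#'
#' @param assess_a,assess_b Assessment tables (name-matched; see
#'   [transition_matrix()]).
#' @return Tibble with `category`, `n_earlier`, `n_later`, `sorensen`.
#' @export
category_turnover <- function(assess_a, assess_b) {
  rows <- lapply(.categories, function(cat) {
    sa <- assess_a$species[assess_a$category == cat]
    sb <- assess_b$species[assess_b$category == cat]
    tibble::tibble(category = cat, n_earlier = length(sa),
                   n_later = length(sb),
                   sorensen = as.numeric(sorensen_dissimilarity(sa, sb)))
  })
  dplyr::bind_rows(rows)
}

#' Apply later identifications to an earlier snapshot
#'
#' Rewrites each record's name (and rank, when the name implies it) in the
#' earlier snapshot to the name it carries in the later snapshot, using the
#' record-level name events of a change log. Coordinates and all other
#' fields are untouched. This puts both snapshots on one taxonomy so that
#' species can be matched by name across years.
#'
#' @param s A `snapshot` (the earlier one).
#' @param events Change log from [diff_snapshots()].
#' @return A `snapshot` with harmonized names.
#' @export
harmonize_names <- function(s, events) {
  name_ev <- events[events$major_class == "name_change", ]
  r <- s$records
  hit <- match(r$record_id, name_ev$record_id)
  repl <- !is.na(hit)
  r$scientific_name[repl] <- name_ev$to_name[hit[repl]]
  r$rank[repl] <- .implied_rank(r$scientific_name[repl])
  out <- s
  out$records <- r
  out
}

#' Per-species EOO change table between two assessments
#'
#' Joins two assessments by species name (earlier side assumed
#' name-harmonized) and reports, for species present in both years, the
#' two EOO values, the direction of the EOO change, whether the category
#' changed, and the threat direction under the ordering
#' LC < NT < VU < EN < CR. Transitions involving DD are reported
#' separately as `from_DD` / `to_DD` (a species DD in both years is
#' `unchanged`).
#'
#' @param assess_a,assess_b Assessment tables.
#' @return Tibble with `species`, `eoo_2007` style columns named
#'   `eoo_earlier`/`eoo_later`, `direction`
#'   (`increased`/`decreased`/`unchanged`), `category_earlier`,
#'   `category_later`, `category_changed`, `threat_direction`.
#' @export
eoo_change_table <- function(assess_a, assess_b) {
  j <- dplyr::inner_join(
    assess_a[, c("species", "eoo_km2", "category")],
    assess_b[, c("species", "eoo_km2", "category")],
    by = "species", suffix = c("_earlier", "_later"))
  names(j)[names(j) == "eoo_km2_earlier"] <- "eoo_earlier"
  names(j)[names(j) == "eoo_km2_later"] <- "eoo_later"
  e_a <- ifelse(is.na(j$eoo_earlier), 0, j$eoo_earlier)
  e_b <- ifelse(is.na(j$eoo_later), 0, j$eoo_later)
  j$direction <- ifelse(e_b > e_a, "increased",
                        ifelse(e_b < e_a, "decreased", "unchanged"))
  j$category_changed <- j$category_earlier != j$category_later
  from_dd <- j$category_earlier == "DD" & j$category_later != "DD"
  to_dd <- j$category_later == "DD" & j$category_earlier != "DD"
  ta <- .threat_order[j$category_earlier]
  tb <- .threat_order[j$category_later]
  j$threat_direction <- ifelse(
    from_dd, "from_DD",
    ifelse(to_dd, "to_DD",
           ifelse(is.na(ta) | is.na(tb), "unchanged",
                  ifelse(tb < ta, "less_threatened",
                         ifelse(tb > ta, "more_threatened", "unchanged")))))
  j
}

#' Summary percentages of an EOO change table
#'
#' @param changes Output of [eoo_change_table()].
#' @param thresholds Criterion B bounds (used to define "threatened" =
#'   VU, EN or CR for the DD-transition split).
#' @return One-row tibble with, over matched species: percent with EOO
#'   increased / decreased / unchanged; percent transitioning to less /
#'   more threatened status (DD transitions excluded from these two);
#'   percent formerly DD now threatened and now not threatened.
#' @export
eoo_change_summary <- function(changes, thresholds = .default_thresholds) {
  n <- nrow(changes)
  threatened <- c("VU", "EN", "CR")
  from_dd <- changes$threat_direction == "from_DD"
  pct <- function(x) if (n > 0) 100 * sum(x) / n else NA_real_
  tibble::tibble(
    n_matched = n,
    pct_eoo_increased = pct(changes$direction == "increased"),
    pct_eoo_decreased = pct(changes$direction == "decreased"),
    pct_eoo_unchanged = pct(changes$direction == "unchanged"),
    pct_less_threatened = pct(changes$threat_direction == "less_threatened"),
    pct_more_threatened = pct(changes$threat_direction == "more_threatened"),
    pct_dd_to_threatened = pct(from_dd &
                                 changes$category_later %in% threatened),
    pct_dd_to_not_threatened = pct(from_dd &
                                     !changes$category_later %in% threatened)
  )
}

#' Bayesian comparison of category counts between two assessments
#'
#' Compares the distribution of species over preliminary categories
#' between snapshots with a Dirichlet-multinomial difference posterior,
#' and the proportion of threatened species (VU, EN or CR among non-DD
#' species) with a Beta-binomial difference posterior. A change is
#' significant when 0 lies outside its 95% credible interval.
#'
#' @param assess_a,assess_b Assessment tables.
#' @param alpha Dirichlet prior pseudo-count (default 1, uniform).
#' @param n_draws Posterior draws (default 10,000).
#' @param seed Optional integer seed.
#' @return List with `categories` (per-category posterior summary plus the
#'   raw counts) and `threatened` (one-row posterior summary for the
#'   threatened proportion).
#' @export
compare_category_counts <- function(assess_a, assess_b, alpha = 1,
                                    n_draws = 10000, seed = NULL) {
  counts_a <- table(factor(assess_a$category, levels = .categories))
  counts_b <- table(factor(assess_b$category, levels = .categories))
  cats <- multinomial_diff_posterior(as.integer(counts_a),
                                     as.integer(counts_b),
                                     alpha = alpha, n_draws = n_draws,
                                     seed = seed, labels = .categories)
  cats$n_earlier <- as.integer(counts_a)
  cats$n_later <- as.integer(counts_b)
  threatened <- c("VU", "EN", "CR")
  non_dd_a <- sum(counts_a[.categories != "DD"])
  non_dd_b <- sum(counts_b[.categories != "DD"])
  thr <- binomial_diff_posterior(
    k_a = sum(counts_a[threatened]), n_a = non_dd_a,
    k_b = sum(counts_b[threatened]), n_b = non_dd_b,
    n_draws = n_draws,
    seed = if (is.null(seed)) NULL else seed + 1L,
    label = "proportion_threatened")
  list(categories = cats, threatened = thr)
}
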