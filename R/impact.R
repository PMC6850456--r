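# One-change-at-a-time counterfactuals: for each specimen change, rebuild
# the affected species' 2007 occurrence set with only that change applied
# (using the 2017 data for the changed specimen), recompute EOO, and
# attribute the difference to the change type.

#' Split correction events into their two species-side tasks
#'
#' A corrected misidentification can alter the EOO of two species: the one
#' that loses the specimen (`correction_out`) and the one that gains it
#' (`correction_in`). Other event rows pass through unchanged.
#'
#' @param events Change log from [diff_snapshots()].
#' @param species_2007 Optional character vector of species names present
#'   in the earlier snapshot; when given, `correction_in` rows whose
#'   gaining species is absent from it are dropped (there is no 2007 EOO
#'   to perturb).
#' @return The event table with `correction` rows replaced by up to two
#'   rows labelled `correction_out` and `correction_in`.
#' @export
expand_corrections <- function(events, species_2007 = NULL) {
  corr <- events$minor_class == "correction"
  if (!any(corr)) return(events)
  base <- events[!corr, ]
  out_rows <- events[corr, ]
  out_rows$minor_class <- "correction_out"
  in_rows <- events[corr, ]
  in_rows$minor_class <- "correction_in"
  if (!is.null(species_2007))
    in_rows <- in_rows[in_rows$to_name %in% species_2007, ]
  dplyr::bind_rows(base, out_rows, in_rows)
}

#' Hypothetical EOO for one attribution task
#'
#' Rebuilds a species' 2007 occurrence set with a single specimen change
#' applied and returns the EOO of the result: an `in` task adds the
#' changed record's 2017 point, an `out` task removes its 2007 point, a
#' `substitute` task replaces the 2007 point with the 2017 one.
#'
#' @param task List with `species`, `direction` (`"in"`, `"out"` or
#'   `"substitute"`), `record_id`, and the relevant `point_2017` /
#'   `point_2007` as `c(latitude, longitude)`.
#' @param occ_2007 Named list of per-species occurrence tibbles with
#'   columns `record_id`, `latitude`, `longitude`; a missing species means
#'   an empty 2007 set.
#' @return Hypothetical EOO in km^2, or `NA` (data-deficient signal).
#' @export
hypothetical_eoo <- function(task, occ_2007) {
  occ <- occ_2007[[task$species]]
  if (is.null(occ))
    occ <- tibble::tibble(record_id = character(), latitude = double(),
                          longitude = double())
  if (task$direction %in% c("out", "substitute")) {
    hit <- which(occ$record_id == task$record_id)
    if (length(hit) != 1)
      stop("record ", task$record_id, " not in the 2007 occurrence set of ",
           task$species, call. = FALSE)
    occ <- occ[-hit, ]
  }
  if (task$direction %in% c("in", "substitute")) {
    occ <- dplyr::bind_rows(occ, tibble::tibble(
      record_id = task$record_id,
      latitude = task$point_2017[1], longitude = task$point_2017[2]))
  }
  compute_eoo(occ$latitude, occ$longitude)
}

# Build the task table from a change log, applying the taxonomic-precedence
# rule and the per-class direction conventions.
.attribution_tasks <- function(events, s2007, s2017) {
  ev <- events[events$minor_class != "new_specimen", ]
  # Taxonomic precedence: a record with both a name and a geography event
  # contributes its name event only.
  name_ids <- ev$record_id[ev$major_class == "name_change"]
  ev <- ev[!(ev$major_class == "geography_change" &
               ev$record_id %in% name_ids), ]
  ev <- ev[ev$minor_class != "nomenclatural", ]
  adds <- events[events$minor_class == "new_specimen", ]
  ev <- dplyr::bind_rows(ev, adds)

  ra <- s2007$records
  rb <- s2017$records
  lat07 <- ra$latitude[match(ev$record_id, ra$record_id)]
  lon07 <- ra$longitude[match(ev$record_id, ra$record_id)]
  lat17 <- rb$latitude[match(ev$record_id, rb$record_id)]
  lon17 <- rb$longitude[match(ev$record_id, rb$record_id)]

  direction_of <- c(new_specimen = "in", lumped = "in", split = "out",
                    upgraded_to_species = "in", downgraded_to_genus = "out",
                    new_coordinates = "in", corrected_coordinates = "substitute")

  rows <- list()
  for (i in seq_len(nrow(ev))) {
    cls <- ev$minor_class[i]
    if (cls == "correction") {
      rows[[length(rows) + 1]] <- tibble::tibble(
        record_id = ev$record_id[i], minor_class = "correction_out",
        species = ev$from_name[i], direction = "out",
        lat_2007 = lat07[i], lon_2007 = lon07[i],
        lat_2017 = lat17[i], lon_2017 = lon17[i])
      rows[[length(rows) + 1]] <- tibble::tibble(
        record_id = ev$record_id[i], minor_class = "correction_in",
        species = ev$to_name[i], direction = "in",
        lat_2007 = lat07[i], lon_2007 = lon07[i],
        lat_2017 = lat17[i], lon_2017 = lon17[i])
    } else {
      dir <- direction_of[[cls]]
      sp <- if (dir == "out") ev$from_name[i] else ev$to_name[i]
      rows[[length(rows) + 1]] <- tibble::tibble(
        record_id = ev$record_id[i], minor_class = cls, species = sp,
        direction = dir,
        lat_2007 = lat07[i], lon_2007 = lon07[i],
        lat_2017 = lat17[i], lon_2017 = lon17[i])
    }
  }
  if (length(rows) == 0) return(tibble::tibble(
    record_id = character(), minor_class = character(),
    species = character(), direction = character(), lat_2007 = double(),
    lon_2007 = double(), lat_2017 = double(), lon_2017 = double()))
  dplyr::bind_rows(rows)
}

#' Attribute hypothetical EOO changes to every specimen change
#'
#' Implements the counterfactual procedure: purely nomenclatural events
#' are excluded (they cannot move locality data); a record with both a
#' taxonomic and a geographic change contributes its taxonomic change
#' only; corrections yield one task per affected species (out for the
#' losing, in for the gaining species); lumps add the specimen to the
#' receiving species, splits remove it from the source species; rank
#' upgrades add, downgrades remove; new coordinates add the newly
#' georeferenced point and corrected coordinates substitute it. For each
#' task the species' hypothetical EOO (2007 data with only that change
#' applied, using 2017 data for the changed specimen) is compared with its
#' 2007 EOO.
#'
#' @param events Change log from [diff_snapshots()].
#' @param s2007,s2017 The two `snapshot`s.
#' @param dd_mode How to treat data-deficient EOOs (fewer than 3 distinct
#'   points): `"zero"` (default) counts them as 0 km^2 in the subtraction
#'   and flags the row with `dd_involved`; `"skip"` drops such rows.
#' @return Tibble of impact records: `record_id`, `minor_class` (with
#'   corrections split in/out), `species`, `direction`, `eoo_2007`,
#'   `hypothetical_eoo`, `delta_eoo` (hypothetical minus 2007),
#'   `dd_involved`. Tasks whose changed specimen lacks the needed
#'   coordinates are dropped and counted in the `n_noop` attribute.
#' @export
attribute_all <- function(events, s2007, s2017,
                          dd_mode = c("zero", "skip")) {
  dd_mode <- match.arg(dd_mode)
  tasks <- .attribution_tasks(events, s2007, s2017)

  # Per-species 2007 occurrence sets (species-rank, georeferenced).
  ra <- s2007$records
  ra <- ra[ra$rank == "species" & !is.na(ra$latitude), ]
  occ_2007 <- split(
    tibble::tibble(record_id = ra$record_id, latitude = ra$latitude,
                   longitude = ra$longitude),
    ra$scientific_name)
  eoo_2007_by_sp <- vapply(occ_2007, function(o)
    compute_eoo(o$latitude, o$longitude), numeric(1))

  need17 <- tasks$direction %in% c("in", "substitute")
  need07 <- tasks$direction %in% c("out", "substitute")
  # No-ops: tasks whose changed specimen lacks the needed coordinates, and
  # tasks whose affected "species" is a bare genus name (no species EOO
  # exists to perturb, e.g. coordinate changes on genus-only records).
  noop <- (need17 & is.na(tasks$lat_2017)) |
    (need07 & is.na(tasks$lat_2007)) |
    .implied_rank(tasks$species) == "genus"
  n_noop <- sum(noop)
  tasks <- tasks[!noop, ]

  n <- nrow(tasks)
  hyp <- numeric(n)
  base <- numeric(n)
  for (i in seq_len(n)) {
    task <- list(species = tasks$species[i],
                 direction = tasks$direction[i],
                 record_id = tasks$record_id[i],
                 point_2007 = c(tasks$lat_2007[i], tasks$lon_2007[i]),
                 point_2017 = c(tasks$lat_2017[i], tasks$lon_2017[i]))
    hyp[i] <- hypothetical_eoo(task, occ_2007)
    base[i] <- if (tasks$species[i] %in% names(eoo_2007_by_sp))
      eoo_2007_by_sp[[tasks$species[i]]] else NA_real_
  }

  out <- tibble::tibble(
    record_id = tasks$record_id, minor_class = tasks$minor_class,
    species = tasks$species, direction = tasks$direction,
    eoo_2007 = base, hypothetical_eoo = hyp)
  out$dd_involved <- is.na(out$eoo_2007) | is.na(out$hypothetical_eoo)
  if (dd_mode == "skip") {
    out <- out[!out$dd_involved, ]
  }
  out$delta_eoo <- ifelse(is.na(out$hypothetical_eoo), 0,
                          out$hypothetical_eoo) -
    ifelse(is.na(out$eoo_2007), 0, out$eoo_2007)
  attr(out, "n_noop") <- n_noop
  out
}

#' Mean hypothetical EOO change per change type
#'
#' @param impacts Impact table from [attribute_all()].
#' @return Tibble per minor class (corrections split in/out): `n`,
#'   `mean_delta_eoo`, `se_delta_eoo` (`NA` when `n` is 1). Classes with
#'   no impacts are omitted.
#' @export
summarize_impacts <- function(impacts) {
  impacts |>
    dplyr::group_by(minor_class = .data$minor_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_delta_eoo = mean(.data$delta_eoo),
      se_delta_eoo = if (dplyr::n() > 1)
        sd(.data$delta_eoo) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop")
}

#' Compare change-type profiles of category-changing vs stable species
#'
#' Builds two multinomial count vectors over change types — events whose
#' affected species did change preliminary category between years versus
#' events whose species did not — and estimates the per-type difference in
#' proportions (changed minus stable) with a Dirichlet difference
#' posterior. A positive significant difference means the change type is
#' overrepresented among category-changing species.
#'
#' @param impacts Impact table from [attribute_all()].
#' @param changed_species Character vector of species whose category
#'   differs between years.
#' @param species_universe Optional character vector; impacts for species
#'   outside it (e.g. absent from the 2007 assessment, so their
#'   category-change status is undefined) are excluded.
#' @param alpha,n_draws,seed Passed to [multinomial_diff_posterior()].
#' @return Tibble with one row per change type: posterior summary plus the
#'   two raw counts (`n_stable`, `n_changed`).
#' @export
compare_change_profiles <- function(impacts, changed_species,
                                    species_universe = NULL, alpha = 1,
                                    n_draws = 10000, seed = NULL) {
  if (!is.null(species_universe))
    impacts <- impacts[impacts$species %in% species_universe, ]
  types <- sort(unique(impacts$minor_class))
  changed <- impacts$species %in% changed_species
  counts_stable <- table(factor(impacts$minor_class[!changed],
                                levels = types))
  counts_changed <- table(factor(impacts$minor_class[changed],
                                 levels = types))
  out <- multinomial_diff_posterior(as.integer(counts_stable),
                                    as.integer(counts_changed),
                                    alpha = alpha, n_draws = n_draws,
                                    seed = seed, labels = types)
  out$n_stable <- as.integer(counts_stable)
  out$n_changed <- as.integer(counts_changed)
  out
}
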