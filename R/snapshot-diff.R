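# Change classes recognised by the differ. Corrections are counted once
# here; the in/out duality is applied downstream in impact attribution.
.minor_classes <- c("new_specimen", "nomenclatural", "lumped", "split",
                    "correction", "upgraded_to_species",
                    "downgraded_to_genus", "new_coordinates",
                    "corrected_coordinates")

.major_of_minor <- c(
  new_specimen = "addition",
  nomenclatural = "name_change", lumped = "name_change",
  split = "name_change", correction = "name_change",
  upgraded_to_species = "name_change", downgraded_to_genus = "name_change",
  new_coordinates = "geography_change",
  corrected_coordinates = "geography_change"
)

# Default coordinate-comparison tolerance: half a minute of arc, suited to
# data georeferenced to the nearest latitude-longitude minute.
.default_geo_tolerance <- 1 / 120

#' Match records of two snapshots by stable identifier
#'
#' @param a,b Earlier and later `snapshot`s.
#' @return A list with `additions` (ids only in `b`), `persisting` (ids in
#'   both) and `disappeared` (ids only in `a`). The three sets partition
#'   the union of ids.
#' @export
match_records <- function(a, b) {
  ids_a <- a$records$record_id
  ids_b <- b$records$record_id
  list(additions = setdiff(ids_b, ids_a),
       persisting = intersect(ids_a, ids_b),
       disappeared = setdiff(ids_a, ids_b))
}

# Vectorised classification of name changes for persisting records whose
# name or rank differs. `pairs` has columns from_name, to_name, from_rank,
# to_rank. Returns minor class + low_confidence flag per row.
.classify_name_pairs <- function(pairs, map, earlier_names, later_names,
                                 earlier_name_counts) {
  n <- nrow(pairs)
  minor <- rep(NA_character_, n)
  lowconf <- rep(FALSE, n)

  # Rank transitions take precedence over everything, including the map.
  up <- pairs$from_rank == "genus" & pairs$to_rank == "species"
  down <- pairs$from_rank == "species" & pairs$to_rank == "genus"
  minor[up] <- "upgraded_to_species"
  minor[down] <- "downgraded_to_genus"

  todo <- is.na(minor)
  if (any(todo)) {
    key <- paste(pairs$from_name, pairs$to_name, sep = "\r")
    if (!is.null(map) && nrow(map) > 0) {
      mkey <- paste(map$from_name, map$to_name, sep = "\r")
      hit <- match(key, mkey)
      mapped <- todo & !is.na(hit)
      action <- map$action[hit[mapped]]
      minor[mapped] <- c(nomenclatural = "nomenclatural", lump = "lumped",
                         split = "split")[action]
      todo <- is.na(minor)
    }
  }

  if (any(todo)) {
    # Per-(from, to) movement statistics over the persisting pairs.
    key <- paste(pairs$from_name, pairs$to_name, sep = "\r")
    n_moved <- as.integer(table(key)[key])
    n_earlier <- earlier_name_counts[pairs$from_name]
    n_earlier[is.na(n_earlier)] <- 0L
    to_in_earlier <- pairs$to_name %in% earlier_names
    from_in_later <- pairs$from_name %in% later_names

    idx <- which(todo)
    for (i in idx) {
      if (to_in_earlier[i]) {
        minor[i] <- "correction"
      } else if (n_moved[i] == n_earlier[i] && !from_in_later[i]) {
        minor[i] <- "lumped"
        lowconf[i] <- TRUE  # heuristic cannot rule out mass correction
      } else if (n_moved[i] < n_earlier[i] && !to_in_earlier[i]) {
        minor[i] <- "split"
      } else {
        minor[i] <- "correction"
      }
    }
  }
  list(minor = minor, low_confidence = lowconf)
}

#' Classify the name change of one persisting record
#'
#' Applies, in order: rank-transition rules (genus to species is
#' `upgraded_to_species`, species to genus `downgraded_to_genus`), the
#' curation map, and a movement heuristic over both snapshots (a move to a
#' name already present earlier is a `correction`; a whole species moving
#' to a name while disappearing itself is a `lumped`, flagged
#' low-confidence; a proper subset moving to a brand-new name is a
#' `split`; anything else a `correction`).
#'
#' @param old,new The record's earlier and later versions (one-row data
#'   frames or lists with `scientific_name` and `rank`).
#' @param map A `curation_map` or `NULL`.
#' @param context List with the earlier and later `snapshot`s
#'   (`list(a = ..., b = ...)`).
#' @return The minor class as a string, or `NA` when name and rank are
#'   unchanged.
#' @export
classify_name_change <- function(old, new, map = NULL, context) {
  if (identical(old$scientific_name, new$scientific_name) &&
        identical(old$rank, new$rank))
    return(NA_character_)
  ra <- context$a$records
  rb <- context$b$records
  pairs <- tibble::tibble(from_name = old$scientific_name,
                          to_name = new$scientific_name,
                          from_rank = old$rank, to_rank = new$rank)
  # Movement statistics need the full persisting join, not just this record.
  joined <- dplyr::inner_join(
    ra[, c("record_id", "scientific_name")],
    rb[, c("record_id", "scientific_name")],
    by = "record_id", suffix = c("_a", "_b"))
  moved_same <- joined$scientific_name_a == old$scientific_name &
    joined$scientific_name_b == new$scientific_name
  counts <- table(ra$scientific_name)
  res <- .classify_name_pairs_single(
    pairs, map,
    earlier_names = ra$scientific_name, later_names = rb$scientific_name,
    n_moved = sum(moved_same), n_earlier = as.integer(counts[old$scientific_name]))
  res
}

.classify_name_pairs_single <- function(pairs, map, earlier_names,
                                        later_names, n_moved, n_earlier) {
  if (pairs$from_rank == "genus" && pairs$to_rank == "species")
    return("upgraded_to_species")
  if (pairs$from_rank == "species" && pairs$to_rank == "genus")
    return("downgraded_to_genus")
  if (!is.null(map) && nrow(map) > 0) {
    hit <- which(map$from_name == pairs$from_name &
                   map$to_name == pairs$to_name)
    if (length(hit) == 1)
      return(c(nomenclatural = "nomenclatural", lump = "lumped",
               split = "split")[[map$action[hit]]])
  }
  if (is.na(n_earlier)) n_earlier <- 0L
  if (pairs$to_name %in% earlier_names) return("correction")
  if (n_moved == n_earlier && !(pairs$from_name %in% later_names))
    return("lumped")
  if (n_moved < n_earlier) return("split")
  "correction"
}

#' Classify the georeference change of one persisting record
#'
#' @param old,new Earlier and later versions of the record (lists or
#'   one-row data frames with `latitude`, `longitude`).
#' @param tolerance Maximum coordinate difference (decimal degrees) treated
#'   as unchanged; default half an arc-minute.
#' @return `"new_coordinates"`, `"corrected_coordinates"`,
#'   `"coordinate_loss"` (an anomaly, not a change class) or `NA` when
#'   unchanged.
#' @export
classify_geo_change <- function(old, new, tolerance = .default_geo_tolerance) {
  old_geo <- !is.na(old$latitude) && !is.na(old$longitude)
  new_geo <- !is.na(new$latitude) && !is.na(new$longitude)
  if (!old_geo && new_geo) return("new_coordinates")
  if (old_geo && !new_geo) return("coordinate_loss")
  if (old_geo && new_geo &&
        (abs(old$latitude - new$latitude) > tolerance ||
           abs(old$longitude - new$longitude) > tolerance))
    return("corrected_coordinates")
  NA_character_
}

.empty_change_log <- function() {
  tibble::tibble(record_id = character(), major_class = character(),
                 minor_class = character(), from_name = character(),
                 to_name = character(), from_latitude = double(),
                 from_longitude = double(), to_latitude = double(),
                 to_longitude = double(), collection_year = integer(),
                 low_confidence = logical())
}

#' Diff two snapshots into a classified change log
#'
#' Produces one `new_specimen` event per addition and, for each record
#' present in both snapshots, at most one name-change event and one
#' geography-change event. Records present only in the earlier snapshot
#' ("disappeared") and records that lost their georeference are reported as
#' attributes, not as change classes.
#'
#' @param a,b Earlier and later `snapshot`s.
#' @param map Optional `curation_map` consulted before the name heuristics.
#' @param tolerance Coordinate tolerance in decimal degrees, see
#'   [classify_geo_change()].
#' @return A tibble with one row per change event (`record_id`,
#'   `major_class`, `minor_class`, `from_name`, `to_name`,
#'   `from_latitude`, `from_longitude`, `to_latitude`, `to_longitude`,
#'   `collection_year` for additions, `low_confidence`), sorted by
#'   `record_id` then class. Attributes: `disappeared` (character vector of
#'   ids), `anomalies` (tibble of coordinate-loss records).
#' @export
diff_snapshots <- function(a, b, map = NULL,
                           tolerance = .default_geo_tolerance) {
  m <- match_records(a, b)
  ra <- a$records
  rb <- b$records

  events <- list()

  if (length(m$additions) > 0) {
    add <- rb[match(m$additions, rb$record_id), ]
    events$additions <- tibble::tibble(
      record_id = add$record_id, major_class = "addition",
      minor_class = "new_specimen", from_name = NA_character_,
      to_name = add$scientific_name, from_latitude = NA_real_,
      from_longitude = NA_real_, to_latitude = add$latitude,
      to_longitude = add$longitude, collection_year = add$collection_year,
      low_confidence = FALSE)
  }

  if (length(m$persisting) > 0) {
    old <- ra[match(m$persisting, ra$record_id), ]
    new <- rb[match(m$persisting, rb$record_id), ]

    name_changed <- old$scientific_name != new$scientific_name |
      old$rank != new$rank
    if (any(name_changed)) {
      pairs <- tibble::tibble(from_name = old$scientific_name[name_changed],
                              to_name = new$scientific_name[name_changed],
                              from_rank = old$rank[name_changed],
                              to_rank = new$rank[name_changed])
      cls <- .classify_name_pairs(
        pairs, map,
        earlier_names = unique(ra$scientific_name),
        later_names = unique(rb$scientific_name),
        earlier_name_counts = table(ra$scientific_name))
      events$names <- tibble::tibble(
        record_id = old$record_id[name_changed],
        major_class = "name_change", minor_class = cls$minor,
        from_name = pairs$from_name, to_name = pairs$to_name,
        from_latitude = NA_real_, from_longitude = NA_real_,
        to_latitude = NA_real_, to_longitude = NA_real_,
        collection_year = NA_integer_,
        low_confidence = cls$low_confidence)
    }

    old_geo <- !is.na(old$latitude) & !is.na(old$longitude)
    new_geo <- !is.na(new$latitude) & !is.na(new$longitude)
    gained <- !old_geo & new_geo
    lost <- old_geo & !new_geo
    moved <- old_geo & new_geo &
      (abs(old$latitude - new$latitude) > tolerance |
         abs(old$longitude - new$longitude) > tolerance)
    geo_changed <- gained | moved
    if (any(geo_changed)) {
      events$geo <- tibble::tibble(
        record_id = old$record_id[geo_changed],
        major_class = "geography_change",
        minor_class = ifelse(gained[geo_changed], "new_coordinates",
                             "corrected_coordinates"),
        from_name = old$scientific_name[geo_changed],
        to_name = new$scientific_name[geo_changed],
        from_latitude = old$latitude[geo_changed],
        from_longitude = old$longitude[geo_changed],
        to_latitude = new$latitude[geo_changed],
        to_longitude = new$longitude[geo_changed],
        collection_year = NA_integer_, low_confidence = FALSE)
    }
    anomalies <- tibble::tibble(record_id = old$record_id[lost],
                                type = rep("coordinate_loss", sum(lost)))
  } else {
    anomalies <- tibble::tibble(record_id = character(), type = character())
  }

  log <- if (length(events) > 0) dplyr::bind_rows(events) else
    .empty_change_log()
  log <- log[order(log$record_id, log$minor_class), ]
  attr(log, "disappeared") <- m$disappeared
  attr(log, "anomalies") <- anomalies
  log
}

#' Tabulate a change log by minor class
#'
#' @param events A change log from [diff_snapshots()].
#' @return Tibble with one row per minor class (all nine, zeros included)
#'   and the count of events.
#' @export
tabulate_changes <- function(events) {
  counts <- table(factor(events$minor_class, levels = .minor_classes))
  tibble::tibble(minor_class = .minor_classes,
                 major_class = unname(.major_of_minor[.minor_classes]),
                 n = as.integer(counts))
}

#' Fraction of additions collected at or before a cutoff year
#'
#' @param events A change log.
#' @param cutoff_year Calendar year.
#' @return One-row tibble: `n_additions`, `n_known_year`, `n_unknown_year`,
#'   `fraction_at_or_before` (over additions with a known collection year;
#'   `NA` when none have one).
#' @export
additions_by_collection_year <- function(events, cutoff_year) {
  add <- events[events$minor_class == "new_specimen", ]
  known <- !is.na(add$collection_year)
  tibble::tibble(
    n_additions = nrow(add),
    n_known_year = sum(known),
    n_unknown_year = sum(!known),
    fraction_at_or_before = if (sum(known) > 0)
      mean(add$collection_year[known] <= cutoff_year) else NA_real_
  )
}

#' Write a change log to a delimited file
#' @param events Change log tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_change_log <- function(events, path) {
  readr::write_csv(events, path, progress = FALSE)
  invisible(path)
}
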