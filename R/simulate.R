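# Seeded generator of paired snapshots with a ground-truth change log,
# emulating the statistical structure of a decade of curation on a large
# monographic specimen database: right-skewed specimens-per-species counts,
# clustered per-species ranges, partial georeferencing, and the nine change
# classes at configurable per-eligible-record rates.

.sim_genus <- "Plantula"

#' Simulation configuration
#'
#' Defaults emulate a curated Neotropical specimen database of roughly 700
#' species with log-normal specimens-per-species counts, bivariate-normal
#' per-species ranges inside a Neotropical bounding box, about 20% of
#' records lacking georeferences, and curation-event rates shaped like a
#' decade of monographic work (nomenclatural renames dominating name
#' changes; lumps, splits, corrections, rank changes and georeferencing
#' changes at realistic lower rates; additions of about 58% of the
#' baseline record count, 79% of them collected at or before the cutoff
#' year).
#'
#' Event rates are probabilities per *eligible* record (or per species for
#' the species-level classes `nomenclatural`, `lumped` and `split`; the
#' default split rate is scaled up by the expected share of a species'
#' records that actually moves in a split, about a third, so the record
#' marginal lands where intended):
#' `upgraded_to_species` applies to genus-rank records,
#' `new_coordinates` to ungeoreferenced records, `corrected_coordinates`
#' to georeferenced records, `correction` and `downgraded_to_genus` to
#' species-rank records without a species-level name event, and
#' `new_specimen` to the baseline record count.
#'
#' @param n_species Number of species.
#' @param specimens_median,specimens_sdlog Log-normal parameters of the
#'   specimens-per-species distribution (median on the natural scale).
#' @param bbox Named vector `lat_min`, `lat_max`, `lon_min`, `lon_max`
#'   (decimal degrees); default approximates the Neotropics.
#' @param range_sd_median,range_sd_sdlog Log-normal parameters of the
#'   per-species range standard deviation (degrees).
#' @param p_ungeoreferenced Probability a record lacks coordinates.
#' @param p_genus_rank Probability a record is only identified to genus.
#' @param event_rates Named probabilities for the nine change classes (see
#'   above for the eligibility base of each).
#' @param p_collected_before_cutoff Probability an added specimen was
#'   collected at or before `cutoff_year`.
#' @param cutoff_year Year separating the two snapshots.
#' @param synonym_pool Size cap for generated synonym/new-species names.
#' @param seed Master seed; each stage derives its own stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 700,
                       specimens_median = 7, specimens_sdlog = 1.1,
                       bbox = c(lat_min = -35, lat_max = 12,
                                lon_min = -82, lon_max = -34),
                       range_sd_median = 0.75, range_sd_sdlog = 0.6,
                       p_ungeoreferenced = 0.2,
                       p_genus_rank = 0.06,
                       event_rates = c(new_specimen = 0.582,
                                       nomenclatural = 0.270,
                                       lumped = 0.0328,
                                       split = 0.033,
                                       correction = 0.061,
                                       upgraded_to_species = 0.72,
                                       downgraded_to_genus = 0.0042,
                                       new_coordinates = 0.116,
                                       corrected_coordinates = 0.010),
                       p_collected_before_cutoff = 0.79,
                       cutoff_year = 2007,
                       synonym_pool = 2000,
                       seed = 1) {
  if (n_species < 1) stop("n_species must be at least 1", call. = FALSE)
  stopifnot(all(c("lat_min", "lat_max", "lon_min", "lon_max") %in%
                  names(bbox)))
  defaults <- eval(formals(sim_config)$event_rates)
  missing_rates <- setdiff(names(defaults), names(event_rates))
  event_rates <- c(event_rates, defaults[missing_rates])[names(defaults)]
  if (any(event_rates < 0 | event_rates > 1))
    stop("event rates must be probabilities", call. = FALSE)
  sp_level <- event_rates[c("nomenclatural", "lumped", "split")]
  if (sum(sp_level) + event_rates["lumped"] > 1)
    stop("species-level event rates too high to assign disjoint species ",
         "(lumps also need untouched receiving species)", call. = FALSE)
  if (event_rates["correction"] + event_rates["downgraded_to_genus"] > 1)
    stop("correction + downgrade rates exceed 1", call. = FALSE)
  if (p_ungeoreferenced < 0 || p_ungeoreferenced >= 1)
    stop("p_ungeoreferenced must be in [0, 1)", call. = FALSE)
  structure(list(
    n_species = as.integer(n_species),
    specimens_median = specimens_median,
    specimens_sdlog = specimens_sdlog,
    bbox = bbox,
    range_sd_median = range_sd_median,
    range_sd_sdlog = range_sd_sdlog,
    p_ungeoreferenced = p_ungeoreferenced,
    p_genus_rank = p_genus_rank,
    event_rates = event_rates,
    p_collected_before_cutoff = p_collected_before_cutoff,
    cutoff_year = as.integer(cutoff_year),
    synonym_pool = as.integer(synonym_pool),
    seed = as.integer(seed)), class = "sim_config")
}

# Round to the nearest arc-minute, stored at the package's 6-decimal
# coordinate precision so truth-log values match stored records exactly.
.round_minute <- function(x) round(round(x * 60) / 60, 6)

.clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate the baseline (earlier) snapshot
#'
#' Species centres are uniform in the bounding box; per-species
#' occurrences are bivariate normal around the centre (clamped to the
#' box) and rounded to the nearest latitude-longitude minute. A fraction
#' of records is stripped of coordinates and a fraction identified only
#' to genus. Deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A `snapshot` labelled by the cutoff year, with a bookkeeping
#'   column `.sim_species` naming each record's true species.
#' @export
generate_baseline_snapshot <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_sp <- config$n_species
  sp_names <- sprintf("%s sp%04d", .sim_genus, seq_len(n_sp))
  n_i <- pmax(1L, as.integer(round(rlnorm(n_sp,
                                          log(config$specimens_median),
                                          config$specimens_sdlog))))
  bb <- config$bbox
  centre_lat <- runif(n_sp, bb["lat_min"], bb["lat_max"])
  centre_lon <- runif(n_sp, bb["lon_min"], bb["lon_max"])
  sd_i <- rlnorm(n_sp, log(config$range_sd_median), config$range_sd_sdlog)

  n_rec <- sum(n_i)
  sp_of <- rep(seq_len(n_sp), n_i)
  lat <- .round_minute(.clamp(rnorm(n_rec, centre_lat[sp_of], sd_i[sp_of]),
                              bb["lat_min"], bb["lat_max"]))
  lon <- .round_minute(.clamp(rnorm(n_rec, centre_lon[sp_of], sd_i[sp_of]),
                              bb["lon_min"], bb["lon_max"]))
  ungeo <- runif(n_rec) < config$p_ungeoreferenced
  lat[ungeo] <- NA_real_
  lon[ungeo] <- NA_real_
  genus_only <- runif(n_rec) < config$p_genus_rank

  records <- tibble::tibble(
    record_id = sprintf("R%06d", seq_len(n_rec)),
    scientific_name = ifelse(genus_only, .sim_genus, sp_names[sp_of]),
    latitude = lat, longitude = lon,
    coord_precision = ifelse(ungeo, NA_character_, "minute"),
    collection_year = sample(1890:config$cutoff_year, n_rec,
                             replace = TRUE),
    databased_year = sample(1995:config$cutoff_year, n_rec, replace = TRUE),
    .sim_species = sp_names[sp_of])
  s <- snapshot(records, label = as.character(config$cutoff_year))
  attr(s, "sim_ranges") <- tibble::tibble(
    species = sp_names, centre_lat = centre_lat, centre_lon = centre_lon,
    sd = sd_i)
  s
}

# Smaller k-means cluster (k = 2) of a species' projected points; returns
# indices into the input. Splits are geographically coherent: the
# peripheral (smaller) cluster moves to the new species.
.split_subset <- function(latitude, longitude) {
  pts <- cbind(latitude, longitude)
  distinct <- unique(pts)
  if (nrow(distinct) < 2) return(1L)  # degenerate: move the first record
  xy <- project_equal_area(latitude, longitude)
  uxy <- unique(xy)
  ucl <- if (nrow(uxy) == 2) c(1L, 2L) else
    suppressWarnings(kmeans(uxy, centers = 2, nstart = 3))$cluster
  assign <- ucl[match(apply(xy, 1, paste, collapse = "\r"),
                      apply(uxy, 1, paste, collapse = "\r"))]
  sizes <- table(assign)
  small <- as.integer(names(sizes)[which.min(sizes)])
  idx <- which(assign == small)
  if (length(idx) == length(latitude)) idx <- idx[-1]  # keep a remainder
  idx
}

.truth_row <- function(record_id, major, minor, from_name = NA_character_,
                       to_name = NA_character_, from_lat = NA_real_,
                       from_lon = NA_real_, to_lat = NA_real_,
                       to_lon = NA_real_, year = NA_integer_) {
  tibble::tibble(record_id = record_id, major_class = major,
                 minor_class = minor, from_name = from_name,
                 to_name = to_name, from_latitude = from_lat,
                 from_longitude = from_lon, to_latitude = to_lat,
                 to_longitude = to_lon, collection_year = year,
                 low_confidence = FALSE)
}

#' Apply a decade of simulated curation events to a baseline snapshot
#'
#' Species-level events first (nomenclatural renames to brand-new synonym
#' names; lumps retiring a whole species into an untouched receiver;
#' splits moving the geographically most peripheral cluster of records to
#' a brand-new name), then record-level name events (corrections moving
#' single records to an existing unchanged species; rank upgrades of
#' genus-only records; rank downgrades), then georeferencing events (first
#' coordinates for ungeoreferenced records; perturbed coordinates for
#' georeferenced ones), then additions with new identifiers. Every event
#' is written to the ground-truth log, and all nomenclatural, lump and
#' split pairs to the emitted curation map. Each record receives at most
#' one name event and one geography event.
#'
#' @param s Baseline snapshot from [generate_baseline_snapshot()].
#' @param config The same [sim_config()].
#' @return List with `snapshot` (the later state, labelled ten years after
#'   the cutoff), `truth` (ground-truth change log in the differ's
#'   format), and `map` (the emitted `curation_map`).
#' @export
apply_curation_events <- function(s, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  rates <- config$event_rates
  bb <- config$bbox
  ranges <- attr(s, "sim_ranges")
  r <- s$records
  truth <- list()
  map_from <- character()
  map_to <- character()
  map_action <- character()
  syn_counter <- 0L
  new_name <- function(stem) {
    syn_counter <<- syn_counter + 1L
    if (syn_counter > config$synonym_pool)
      stop("synonym pool exhausted; increase synonym_pool", call. = FALSE)
    sprintf("%s %s%04d", .sim_genus, stem, syn_counter)
  }

  species <- sort(unique(r$scientific_name[r$rank == "species"]))
  n_sp <- length(species)
  u <- runif(n_sp)
  p_nom <- rates["nomenclatural"]
  p_lump <- rates["lumped"]
  p_split <- rates["split"]
  ev_sp <- ifelse(u < p_nom, "nom",
                  ifelse(u < p_nom + p_lump, "lump",
                         ifelse(u < p_nom + p_lump + p_split, "split",
                                "none")))
  names(ev_sp) <- species
  untouched <- species[ev_sp == "none"]
  lumps <- species[ev_sp == "lump"]
  if (length(lumps) > length(untouched)) {
    keep <- seq_len(length(untouched))
    ev_sp[lumps[-keep]] <- "none"
    untouched <- species[ev_sp == "none"]
    lumps <- species[ev_sp == "lump"]
  }
  receivers <- if (length(lumps) > 0)
    sample(untouched, length(lumps)) else character()
  names(receivers) <- lumps

  new_names <- r$scientific_name  # later name per record
  new_rank <- r$rank
  has_name_event <- rep(FALSE, nrow(r))

  # Nomenclatural renames: the whole species takes a brand-new name.
  for (sp in species[ev_sp == "nom"]) {
    nn <- new_name("nomen")
    idx <- which(r$scientific_name == sp)
    new_names[idx] <- nn
    has_name_event[idx] <- TRUE
    truth[[length(truth) + 1]] <- .truth_row(
      r$record_id[idx], "name_change", "nomenclatural", sp, nn)
    map_from <- c(map_from, sp); map_to <- c(map_to, nn)
    map_action <- c(map_action, "nomenclatural")
  }

  # Lumps: every record of the retired species joins the receiver.
  for (sp in lumps) {
    to <- receivers[[sp]]
    idx <- which(r$scientific_name == sp)
    new_names[idx] <- to
    has_name_event[idx] <- TRUE
    truth[[length(truth) + 1]] <- .truth_row(
      r$record_id[idx], "name_change", "lumped", sp, to)
    map_from <- c(map_from, sp); map_to <- c(map_to, to)
    map_action <- c(map_action, "lump")
  }

  # Splits: the peripheral cluster moves to a brand-new species.
  for (sp in species[ev_sp == "split"]) {
    idx <- which(r$scientific_name == sp)
    geo <- idx[!is.na(r$latitude[idx])]
    if (length(idx) < 2 || length(geo) < 1) next
    moved <- if (length(geo) >= 2)
      geo[.split_subset(r$latitude[geo], r$longitude[geo])] else geo
    if (length(moved) >= length(idx)) moved <- moved[-1]
    if (length(moved) == 0) next
    nn <- new_name("nova")
    new_names[moved] <- nn
    has_name_event[moved] <- TRUE
    truth[[length(truth) + 1]] <- .truth_row(
      r$record_id[moved], "name_change", "split", sp, nn)
    map_from <- c(map_from, sp); map_to <- c(map_to, nn)
    map_action <- c(map_action, "split")
  }

  # Record-level name events on records without a species-level event.
  stable_names <- species[ev_sp %in% c("none", "split")]
  eligible <- which(r$rank == "species" & !has_name_event)
  if (length(eligible) > 0 && length(stable_names) > 1) {
    u2 <- runif(length(eligible))
    corr <- eligible[u2 < rates["correction"]]
    down <- eligible[u2 >= rates["correction"] &
                       u2 < rates["correction"] +
                         rates["downgraded_to_genus"]]
    for (i in corr) {
      choices <- setdiff(stable_names, r$scientific_name[i])
      if (length(choices) == 0) next
      to <- if (length(choices) == 1) choices else sample(choices, 1)
      truth[[length(truth) + 1]] <- .truth_row(
        r$record_id[i], "name_change", "correction",
        r$scientific_name[i], to)
      new_names[i] <- to
      has_name_event[i] <- TRUE
    }
    if (length(down) > 0) {
      truth[[length(truth) + 1]] <- .truth_row(
        r$record_id[down], "name_change", "downgraded_to_genus",
        r$scientific_name[down], .sim_genus)
      new_names[down] <- .sim_genus
      new_rank[down] <- "genus"
      has_name_event[down] <- TRUE
    }
  }

  # Rank upgrades: genus-only records fully determined to their true
  # species, provided that species' name did not itself move.
  genus_idx <- which(r$rank == "genus")
  if (length(genus_idx) > 0) {
    ok <- r$.sim_species[genus_idx] %in%
      c(stable_names, setdiff(r$.sim_species, species))
    up <- genus_idx[ok & runif(length(genus_idx)) <
                      rates["upgraded_to_species"]]
    if (length(up) > 0) {
      truth[[length(truth) + 1]] <- .truth_row(
        r$record_id[up], "name_change", "upgraded_to_species",
        .sim_genus, r$.sim_species[up])
      new_names[up] <- r$.sim_species[up]
      new_rank[up] <- "species"
      has_name_event[up] <- TRUE
    }
  }

  # Georeferencing events.
  new_lat <- r$latitude
  new_lon <- r$longitude
  new_prec <- r$coord_precision
  sp_row <- match(r$.sim_species, ranges$species)
  ungeo <- which(is.na(r$latitude) & new_rank == "species")
  if (length(ungeo) > 0) {
    gain <- ungeo[runif(length(ungeo)) < rates["new_coordinates"]]
    if (length(gain) > 0) {
      g <- sp_row[gain]
      glat <- .round_minute(.clamp(rnorm(length(gain), ranges$centre_lat[g],
                                         ranges$sd[g]),
                                   bb["lat_min"], bb["lat_max"]))
      glon <- .round_minute(.clamp(rnorm(length(gain), ranges$centre_lon[g],
                                         ranges$sd[g]),
                                   bb["lon_min"], bb["lon_max"]))
      new_lat[gain] <- glat
      new_lon[gain] <- glon
      new_prec[gain] <- "minute"
      truth[[length(truth) + 1]] <- .truth_row(
        r$record_id[gain], "geography_change", "new_coordinates",
        r$scientific_name[gain], new_names[gain],
        NA_real_, NA_real_, glat, glon)
    }
  }
  geo <- which(!is.na(r$latitude))
  if (length(geo) > 0) {
    fix <- geo[runif(length(geo)) < rates["corrected_coordinates"]]
    if (length(fix) > 0) {
      # Shift each coordinate by 3-30 arc-minutes towards the box centre,
      # so the change always exceeds the differ's half-minute tolerance.
      mid_lat <- mean(bb[c("lat_min", "lat_max")])
      mid_lon <- mean(bb[c("lon_min", "lon_max")])
      dlat <- runif(length(fix), 0.05, 0.5) *
        ifelse(r$latitude[fix] > mid_lat, -1, 1)
      dlon <- runif(length(fix), 0.05, 0.5) *
        ifelse(r$longitude[fix] > mid_lon, -1, 1)
      flat <- .round_minute(r$latitude[fix] + dlat)
      flon <- .round_minute(r$longitude[fix] + dlon)
      new_lat[fix] <- flat
      new_lon[fix] <- flon
      truth[[length(truth) + 1]] <- .truth_row(
        r$record_id[fix], "geography_change", "corrected_coordinates",
        r$scientific_name[fix], new_names[fix],
        r$latitude[fix], r$longitude[fix], flat, flon)
    }
  }

  # Additions: new identifiers, assigned to species in proportion to
  # their baseline sizes, named by their 2017 identity.
  n_add <- rbinom(1, nrow(r), rates["new_specimen"])
  additions <- NULL
  if (n_add > 0) {
    base_sp <- r$.sim_species[r$rank == "species" | r$rank == "genus"]
    pick <- sample(r$.sim_species, n_add, replace = TRUE)
    g <- match(pick, ranges$species)
    alat <- .round_minute(.clamp(rnorm(n_add, ranges$centre_lat[g],
                                       ranges$sd[g]),
                                 bb["lat_min"], bb["lat_max"]))
    alon <- .round_minute(.clamp(rnorm(n_add, ranges$centre_lon[g],
                                       ranges$sd[g]),
                                 bb["lon_min"], bb["lon_max"]))
    aungeo <- runif(n_add) < config$p_ungeoreferenced
    alat[aungeo] <- NA_real_
    alon[aungeo] <- NA_real_
    # 2017 identity of each receiving species.
    later_of <- stats::setNames(pick, NULL)
    renames <- c(
      stats::setNames(map_to[map_action != "split"],
                      map_from[map_action != "split"]))
    hit <- match(later_of, names(renames))
    later_of[!is.na(hit)] <- renames[hit[!is.na(hit)]]
    before <- runif(n_add) < config$p_collected_before_cutoff
    cyear <- ifelse(before,
                    sample(1890:config$cutoff_year, n_add, replace = TRUE),
                    sample((config$cutoff_year + 1):(config$cutoff_year + 10),
                           n_add, replace = TRUE))
    additions <- tibble::tibble(
      record_id = sprintf("A%06d", seq_len(n_add)),
      scientific_name = later_of,
      latitude = alat, longitude = alon,
      coord_precision = ifelse(aungeo, NA_character_, "minute"),
      collection_year = as.integer(cyear),
      databased_year = sample((config$cutoff_year + 1):
                                (config$cutoff_year + 10), n_add,
                              replace = TRUE),
      .sim_species = pick)
    truth[[length(truth) + 1]] <- .truth_row(
      additions$record_id, "addition", "new_specimen",
      to_name = additions$scientific_name,
      to_lat = additions$latitude, to_lon = additions$longitude,
      year = additions$collection_year)
  }

  later <- tibble::tibble(
    record_id = r$record_id, scientific_name = new_names,
    latitude = new_lat, longitude = new_lon, coord_precision = new_prec,
    collection_year = r$collection_year,
    databased_year = r$databased_year, .sim_species = r$.sim_species)
  if (!is.null(additions)) later <- dplyr::bind_rows(later, additions)

  truth_log <- if (length(truth) > 0) dplyr::bind_rows(truth) else
    .empty_change_log()
  truth_log <- truth_log[order(truth_log$record_id,
                               truth_log$minor_class), ]
  list(snapshot = snapshot(later,
                           label = as.character(config$cutoff_year + 10)),
       truth = truth_log,
       map = curation_map(map_from, map_to, map_action))
}

#' Generate a paired-snapshot simulation with ground truth
#'
#' Convenience composition of [generate_baseline_snapshot()] and
#' [apply_curation_events()].
#'
#' @param config A [sim_config()].
#' @return List with `a` (earlier snapshot), `b` (later snapshot),
#'   `truth` (ground-truth change log) and `map` (emitted curation map).
#' @export
generate_pair <- function(config) {
  a <- generate_baseline_snapshot(config)
  cur <- apply_curation_events(a, config)
  list(a = a, b = cur$snapshot, truth = cur$truth, map = cur$map)
}
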