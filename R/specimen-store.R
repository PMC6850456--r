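#' @importFrom stats rnorm runif rbeta rgamma rlnorm rbinom sd quantile kmeans
#' @importFrom utils head
NULL

# Canonical record columns, in storage order. Extra columns are preserved
# after these.
.record_cols <- c("record_id", "scientific_name", "rank",
                  "latitude", "longitude", "coord_precision",
                  "collection_year", "databased_year")

# Darwin Core (and common) aliases accepted in input headers.
.column_aliases <- c(
  occurrenceID     = "record_id",
  occurrenceid     = "record_id",
  id               = "record_id",
  scientificName   = "scientific_name",
  scientificname   = "scientific_name",
  decimalLatitude  = "latitude",
  decimallatitude  = "latitude",
  decimalLongitude = "longitude",
  decimallongitude = "longitude",
  taxonRank        = "rank",
  taxonrank        = "rank",
  year             = "collection_year"
)

#' Convert a degrees-minutes-seconds coordinate to decimal degrees
#'
#' Herbarium databases often store localities as degree, minute, second
#' triplets with a hemisphere letter. This converts them to signed decimal
#' degrees (southern and western hemispheres negative). All arguments are
#' vectorised and recycled.
#'
#' @param degrees Non-negative integer degrees.
#' @param minutes Integer minutes in `[0, 60)`.
#' @param seconds Numeric seconds in `[0, 60)`.
#' @param hemisphere One of `"N"`, `"S"`, `"E"`, `"W"`.
#' @return Decimal degrees, negative for `S` and `W`.
#' @examples
#' parse_dms_coordinate(10, 30, 0, "S")  # -10.5
#' @export
parse_dms_coordinate <- function(degrees, minutes, seconds, hemisphere) {
  n <- max(length(degrees), length(minutes), length(seconds),
           length(hemisphere))
  degrees <- rep_len(degrees, n)
  minutes <- rep_len(minutes, n)
  seconds <- rep_len(seconds, n)
  hemisphere <- rep_len(as.character(hemisphere), n)
  if (any(is.na(degrees) | degrees < 0 | degrees != floor(degrees)))
    stop("degrees must be non-negative integers", call. = FALSE)
  if (any(is.na(minutes) | minutes < 0 | minutes >= 60 |
            minutes != floor(minutes)))
    stop("minutes must be integers in [0, 60)", call. = FALSE)
  if (any(is.na(seconds) | seconds < 0 | seconds >= 60))
    stop("seconds must be numbers in [0, 60)", call. = FALSE)
  if (!all(hemisphere %in% c("N", "S", "E", "W")))
    stop("hemisphere must be one of N, S, E, W", call. = FALSE)
  value <- degrees + minutes / 60 + seconds / 3600
  sign <- ifelse(hemisphere %in% c("S", "W"), -1, 1)
  lat_like <- hemisphere %in% c("N", "S")
  if (any(lat_like & value > 90))
    stop("latitude magnitude exceeds 90 degrees", call. = FALSE)
  if (any(!lat_like & value > 180))
    stop("longitude magnitude exceeds 180 degrees", call. = FALSE)
  sign * value
}

# Rank implied by a scientific name: one word = genus, more = species.
.implied_rank <- function(scientific_name) {
  ifelse(grepl("\\s", trimws(scientific_name)), "species", "genus")
}

#' Construct a specimen snapshot
#'
#' A snapshot is one dated state of the specimen database: a set of records
#' keyed by a stable identifier. Records are validated against the data
#' model: unique non-empty `record_id`, rank consistent with the presence of
#' a species epithet, and latitude/longitude either both present or both
#' absent (a record is "georeferenced" iff both are present).
#'
#' @param records A data frame with at least `record_id` and
#'   `scientific_name`; optional `rank`, `latitude`, `longitude`,
#'   `coord_precision`, `collection_year`, `databased_year`. Extra columns
#'   are kept untouched.
#' @param label Free-text label for the snapshot (e.g. a year).
#' @return An object of class `snapshot`: a list with `label` and a
#'   `records` tibble (coordinates rounded to 6 decimals).
#' @export
snapshot <- function(records, label = "") {
  records <- tibble::as_tibble(records)
  if (!all(c("record_id", "scientific_name") %in% names(records)))
    stop("records need at least record_id and scientific_name", call. = FALSE)
  records$record_id <- as.character(records$record_id)
  records$scientific_name <- trimws(as.character(records$scientific_name))
  for (col in c("latitude", "longitude")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
    records[[col]] <- round(as.numeric(records[[col]]), 6)
  }
  if (!"coord_precision" %in% names(records))
    records$coord_precision <- ifelse(is.na(records$latitude),
                                      NA_character_, "decimal")
  for (col in c("collection_year", "databased_year")) {
    if (!col %in% names(records)) records[[col]] <- NA_integer_
    records[[col]] <- as.integer(records[[col]])
  }
  implied <- .implied_rank(records$scientific_name)
  if (!"rank" %in% names(records)) {
    records$rank <- implied
  } else {
    records$rank <- as.character(records$rank)
    bad <- which(!is.na(records$rank) & records$rank != implied)
    if (length(bad) > 0)
      stop("rank inconsistent with scientific name on rows: ",
           paste(head(bad, 10), collapse = ", "), call. = FALSE)
    records$rank[is.na(records$rank)] <- implied[is.na(records$rank)]
  }
  .validate_records(records)
  extra <- setdiff(names(records), .record_cols)
  records <- records[, c(.record_cols, extra)]
  structure(list(label = as.character(label), records = records),
            class = "snapshot")
}

.validate_records <- function(records) {
  if (any(is.na(records$record_id) | records$record_id == ""))
    stop("record_id must be non-empty", call. = FALSE)
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup) > 0) {
    rows <- which(records$record_id %in% dup)
    stop("duplicated record_id (", paste(unique(dup), collapse = ", "),
         ") on rows: ", paste(rows, collapse = ", "), call. = FALSE)
  }
  half <- which(is.na(records$latitude) != is.na(records$longitude))
  if (length(half) > 0)
    stop("latitude without longitude (or vice versa) on rows: ",
         paste(half, collapse = ", "), call. = FALSE)
  bad_lat <- which(!is.na(records$latitude) & abs(records$latitude) > 90)
  bad_lon <- which(!is.na(records$longitude) & abs(records$longitude) > 180)
  if (length(bad_lat) > 0 || length(bad_lon) > 0)
    stop("coordinates out of range on rows: ",
         paste(union(bad_lat, bad_lon), collapse = ", "), call. = FALSE)
  if (!all(records$rank %in% c("species", "genus")))
    stop("rank must be 'species' or 'genus'", call. = FALSE)
  invisible(records)
}

#' @export
print.snapshot <- function(x, ...) {
  cat("<snapshot '", x$label, "': ", nrow(x$records), " records, ",
      length(unique(x$records$scientific_name[x$records$rank == "species"])),
      " species>\n", sep = "")
  invisible(x)
}

#' Is a record georeferenced?
#' @param s A `snapshot`.
#' @return Logical vector, one entry per record.
#' @export
is_georeferenced <- function(s) {
  !is.na(s$records$latitude) & !is.na(s$records$longitude)
}

#' Read a snapshot from a delimited text file
#'
#' Accepts comma- or tab-separated files with a header. Column names may be
#' the package's plain names or Darwin Core terms (`occurrenceID`,
#' `scientificName`, `decimalLatitude`, `decimalLongitude`). Coordinates may
#' alternatively be supplied as DMS columns (`lat_deg`, `lat_min`,
#' `lat_sec`, `lat_hem` and the `lon_*` counterparts), which are converted
#' with [parse_dms_coordinate()] and recorded at second (or minute, when all
#' seconds are zero) precision. Unknown extra columns are preserved.
#'
#' @param path Path to a delimited UTF-8 text file.
#' @param label Snapshot label; defaults to the file name.
#' @param delim Field delimiter; guessed from the first line when `NULL`.
#' @return A `snapshot`.
#' @export
read_snapshot <- function(path, label = NULL, delim = NULL) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(raw) <- ifelse(names(raw) %in% names(.column_aliases),
                       .column_aliases[names(raw)], names(raw))
  dms_lat <- all(c("lat_deg", "lat_min", "lat_hem") %in% names(raw))
  dms_lon <- all(c("lon_deg", "lon_min", "lon_hem") %in% names(raw))
  if (dms_lat != dms_lon)
    stop("DMS columns must be given for both latitude and longitude",
         call. = FALSE)
  if (dms_lat && dms_lon) {
    lat_sec <- if ("lat_sec" %in% names(raw)) raw$lat_sec else 0
    lon_sec <- if ("lon_sec" %in% names(raw)) raw$lon_sec else 0
    lat_sec[is.na(lat_sec)] <- 0
    lon_sec[is.na(lon_sec)] <- 0
    has <- !is.na(raw$lat_deg)
    if (any(has != !is.na(raw$lon_deg)))
      stop("DMS latitude without longitude", call. = FALSE)
    raw$latitude <- NA_real_
    raw$longitude <- NA_real_
    raw$latitude[has] <- parse_dms_coordinate(raw$lat_deg[has],
                                              raw$lat_min[has],
                                              lat_sec[has],
                                              raw$lat_hem[has])
    raw$longitude[has] <- parse_dms_coordinate(raw$lon_deg[has],
                                               raw$lon_min[has],
                                               lon_sec[has],
                                               raw$lon_hem[has])
    raw$coord_precision <- ifelse(!has, NA_character_,
                                  if (all(lat_sec == 0 & lon_sec == 0))
                                    "minute" else "second")
    raw <- raw[, setdiff(names(raw), c("lat_deg", "lat_min", "lat_sec",
                                       "lat_hem", "lon_deg", "lon_min",
                                       "lon_sec", "lon_hem"))]
  }
  snapshot(raw, label = label)
}

#' Write a snapshot to a delimited text file
#'
#' @param s A `snapshot`.
#' @param path Output path; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(s, path) {
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(s$records, path, progress = FALSE)
  } else {
    readr::write_csv(s$records, path, progress = FALSE)
  }
  invisible(path)
}

#' Summarise a snapshot
#'
#' @param s A `snapshot`.
#' @return One-row tibble: `label`, `n_records`, `n_species` (distinct
#'   species-rank names), `mean_specimens_per_species` (`NA` when there are
#'   no species), `n_georeferenced`, `frac_georeferenced`.
#' @export
snapshot_summary <- function(s) {
  r <- s$records
  sp <- r$scientific_name[r$rank == "species"]
  n_sp <- length(unique(sp))
  n_geo <- sum(is_georeferenced(s))
  tibble::tibble(
    label = s$label,
    n_records = nrow(r),
    n_species = n_sp,
    mean_specimens_per_species = if (n_sp > 0) length(sp) / n_sp else NA_real_,
    n_georeferenced = n_geo,
    frac_georeferenced = if (nrow(r) > 0) n_geo / nrow(r) else NA_real_
  )
}

#' Construct a curation map
#'
#' A curation map records specialist knowledge about name changes between
#' snapshots: each entry maps an old name to a new name with the curatorial
#' action behind it (`nomenclatural` renaming, a `lump` of one species into
#' another, or a `split` of a subset into a newly recognised species). The
#' change classifier consults it before falling back to heuristics.
#'
#' @param from_name,to_name Character vectors of old and new names.
#' @param action Character vector: `"nomenclatural"`, `"lump"` or `"split"`.
#' @return A tibble of class `curation_map`.
#' @export
curation_map <- function(from_name = character(), to_name = character(),
                         action = character()) {
  m <- tibble::tibble(from_name = as.character(from_name),
                      to_name = as.character(to_name),
                      action = as.character(action))
  if (nrow(m) > 0) {
    if (!all(m$action %in% c("nomenclatural", "lump", "split")))
      stop("action must be nomenclatural, lump or split", call. = FALSE)
    if (any(m$from_name == m$to_name))
      stop("curation map entries must change the name", call. = FALSE)
    key <- paste(m$from_name, m$to_name, sep = "\r")
    if (anyDuplicated(key))
      stop("conflicting curation map entries for pair(s): ",
           paste(unique(m$from_name[duplicated(key)]), collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(m$from_name))
      stop("multiple curation map entries for from_name(s): ",
           paste(unique(m$from_name[duplicated(m$from_name)]),
                 collapse = ", "), call. = FALSE)
  }
  class(m) <- c("curation_map", class(m))
  m
}

#' Read a curation map from a 3-column delimited file
#'
#' @param path File with columns `from_name`, `to_name`, `action`.
#' @param delim Delimiter; guessed when `NULL`.
#' @return A `curation_map`.
#' @export
read_curation_map <- function(path, delim = NULL) {
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  m <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  curation_map(m$from_name, m$to_name, m$action)
}

#' Write a curation map
#' @param map A `curation_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curation_map <- function(map, path) {
  readr::write_csv(map, path, progress = FALSE)
  invisible(path)
}
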