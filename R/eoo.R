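# Authalic sphere radius (km) used for all equal-area projection scaling.
.earth_radius_km <- 6371.0072

# Preliminary Criterion B thresholds (km^2). EOO below the first three
# bounds gives CR / EN / VU; the NT bound is a widely used convention on
# top of Criterion B, which itself defines no NT threshold.
.default_thresholds <- c(CR = 100, EN = 5000, VU = 20000, NT = 30000)

.categories <- c("CR", "EN", "VU", "NT", "LC", "DD")
# Threat ordering, least to most threatened; DD sits outside the ordering.
.threat_order <- c(LC = 1, NT = 2, VU = 3, EN = 4, CR = 5)

#' Project occurrence points to planar kilometres, preserving area
#'
#' Cylindrical equal-area projection on an authalic sphere, with the
#' standard parallel and central meridian placed at the centroid of the
#' input points so that local shape distortion is small where the points
#' are. Exactly area-preserving on the sphere.
#'
#' @param latitude,longitude Decimal-degree coordinate vectors.
#' @return A two-column matrix (`x`, `y`) in kilometres, centred on the
#'   point centroid.
#' @export
project_equal_area <- function(latitude, longitude) {
  if (length(latitude) < 1) stop("at least one point required", call. = FALSE)
  if (diff(range(longitude)) >= 180)
    stop("longitudinal span of 180 degrees or more: split the data at the ",
         "antimeridian or recentre longitudes before projecting",
         call. = FALSE)
  lat0 <- mean(latitude) * pi / 180
  lon0 <- mean(longitude)
  coslat0 <- cos(lat0)
  x <- .earth_radius_km * coslat0 * (longitude - lon0) * pi / 180
  y <- .earth_radius_km * (sin(latitude * pi / 180) - sin(lat0)) / coslat0
  cbind(x = x, y = y)
}

# Shoelace area of a polygon given vertices in order (any orientation).
.shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Area of the minimum convex polygon around occurrence points
#'
#' Projects the points with [project_equal_area()], takes the convex hull,
#' and returns its planar area. Collinear point sets have zero area.
#'
#' @param latitude,longitude Decimal-degree coordinate vectors (at least 3
#'   distinct points).
#' @return Area in square kilometres, or `NA` when fewer than 3 distinct
#'   points remain after deduplication (the data-deficient signal).
#' @export
convex_hull_area_km2 <- function(latitude, longitude) {
  pts <- unique(cbind(latitude, longitude))
  if (nrow(pts) < 3) return(NA_real_)
  xy <- project_equal_area(pts[, 1], pts[, 2])
  h <- grDevices::chull(xy[, 1], xy[, 2])
  .shoelace_area(xy[h, 1], xy[h, 2])
}

#' Extent of occurrence of one species' occurrence set
#'
#' EOO is the area of the minimum convex polygon enclosing all distinct
#' georeferenced occurrence points. Species with fewer than 3 distinct
#' points cannot support an EOO and yield the data-deficient signal `NA`.
#' Collinear sets yield 0 (EOO is computable, merely degenerate).
#'
#' @param latitude,longitude Decimal-degree vectors; `NA` pairs (records
#'   without a georeference) are dropped.
#' @return EOO in square kilometres, or `NA` (data deficient).
#' @export
compute_eoo <- function(latitude, longitude) {
  keep <- !is.na(latitude) & !is.na(longitude)
  convex_hull_area_km2(latitude[keep], longitude[keep])
}

#' Assign a preliminary IUCN Criterion B category from an EOO value
#'
#' Categories use strict thresholds on EOO alone (no subcriteria): below
#' the CR bound is CR, then EN, VU, NT, and LC at or above the NT bound.
#' The data-deficient signal (`NA`) maps to DD.
#'
#' @param eoo_km2 Numeric vector of EOO values (km^2), `NA` for DD.
#' @param thresholds Named, strictly increasing vector of CR/EN/VU/NT
#'   bounds in km^2.
#' @return Character vector of categories.
#' @export
categorize_eoo <- function(eoo_km2, thresholds = .default_thresholds) {
  if (length(thresholds) != 4 || any(diff(thresholds) <= 0))
    stop("thresholds must be 4 strictly increasing values (CR, EN, VU, NT)",
         call. = FALSE)
  out <- rep("LC", length(eoo_km2))
  out[eoo_km2 < thresholds[4]] <- "NT"
  out[eoo_km2 < thresholds[3]] <- "VU"
  out[eoo_km2 < thresholds[2]] <- "EN"
  out[eoo_km2 < thresholds[1]] <- "CR"
  out[is.na(eoo_km2)] <- "DD"
  out
}

#' Preliminary conservation assessment of every species in a snapshot
#'
#' Computes, per distinct species-rank name, the number of records, of
#' georeferenced records and of distinct georeferenced points, the EOO and
#' the preliminary Criterion B category. Genus-rank records are excluded.
#' Species whose records yield fewer than 3 distinct points are DD.
#'
#' @param s A `snapshot`.
#' @param thresholds Criterion B bounds, see [categorize_eoo()].
#' @return Tibble with columns `species`, `n_records`, `n_georeferenced`,
#'   `n_distinct_points`, `eoo_km2` (`NA` for DD), `category`.
#' @export
assess_snapshot <- function(s, thresholds = .default_thresholds) {
  r <- s$records[s$records$rank == "species", ]
  if (nrow(r) == 0)
    return(tibble::tibble(species = character(), n_records = integer(),
                          n_georeferenced = integer(),
                          n_distinct_points = integer(),
                          eoo_km2 = double(), category = character()))
  out <- r |>
    dplyr::group_by(species = .data$scientific_name) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      n_georeferenced = sum(!is.na(.data$latitude)),
      n_distinct_points = nrow(unique(cbind(
        .data$latitude[!is.na(.data$latitude)],
        .data$longitude[!is.na(.data$longitude)]))),
      eoo_km2 = compute_eoo(.data$latitude, .data$longitude),
      .groups = "drop")
  out$category <- categorize_eoo(out$eoo_km2, thresholds)
  out[order(out$species), ]
}

#' Gridded specimen and species counts on a fixed equal-area grid
#'
#' Counts georeferenced specimens and distinct species per cell of a fixed
#' global cylindrical equal-area grid (standard parallel at the equator)
#' with square cells of the configured area. The fixed grid makes counts
#' comparable across snapshots.
#'
#' @param s A `snapshot`.
#' @param cell_area_km2 Cell area; default 10,000 km^2 (100 km squares).
#' @return Tibble with `cell_id` (stable string key), `cell_x`, `cell_y`
#'   (integer grid indices), `centroid_latitude`, `centroid_longitude`,
#'   `specimen_count`, `species_count`.
#' @export
grid_counts <- function(s, cell_area_km2 = 10000) {
  geo <- is_georeferenced(s)
  r <- s$records[geo, ]
  if (nrow(r) == 0)
    return(tibble::tibble(cell_id = character(), cell_x = integer(),
                          cell_y = integer(), centroid_latitude = double(),
                          centroid_longitude = double(),
                          specimen_count = integer(),
                          species_count = integer()))
  side <- sqrt(cell_area_km2)
  R <- .earth_radius_km
  x <- R * r$longitude * pi / 180
  y <- R * sin(r$latitude * pi / 180)
  cx <- as.integer(floor(x / side))
  cy <- as.integer(floor(y / side))
  d <- tibble::tibble(cell_x = cx, cell_y = cy,
                      species = ifelse(r$rank == "species",
                                       r$scientific_name, NA_character_))
  out <- d |>
    dplyr::group_by(.data$cell_x, .data$cell_y) |>
    dplyr::summarise(specimen_count = dplyr::n(),
                     species_count = dplyr::n_distinct(
                       .data$species[!is.na(.data$species)]),
                     .groups = "drop")
  out$cell_id <- paste(out$cell_x, out$cell_y, sep = ":")
  out$centroid_longitude <- ((out$cell_x + 0.5) * side / R) * 180 / pi
  out$centroid_latitude <- asin(pmin(1, pmax(-1, (out$cell_y + 0.5) *
                                               side / R))) * 180 / pi
  out[, c("cell_id", "cell_x", "cell_y", "centroid_latitude",
          "centroid_longitude", "specimen_count", "species_count")]
}

#' Difference of two gridded count tables (later minus earlier)
#'
#' @param g_a,g_b Grid tables from [grid_counts()] for the earlier and
#'   later snapshot (same cell size).
#' @return Tibble with per-cell `specimen_diff` and `species_diff`;
#'   cells present in either table are included (missing counts are 0).
#' @export
grid_diff <- function(g_a, g_b) {
  j <- dplyr::full_join(g_a, g_b, by = c("cell_id", "cell_x", "cell_y",
                                         "centroid_latitude",
                                         "centroid_longitude"),
                        suffix = c("_a", "_b"))
  for (col in c("specimen_count_a", "specimen_count_b",
                "species_count_a", "species_count_b"))
    j[[col]][is.na(j[[col]])] <- 0L
  j$specimen_diff <- j$specimen_count_b - j$specimen_count_a
  j$species_diff <- j$species_count_b - j$species_count_a
  j
}
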