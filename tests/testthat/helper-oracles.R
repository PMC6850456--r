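# Independent oracles and fixture builders shared across tests.

# Brute-force convex hull by gift wrapping (Jarvis march) plus shoelace
# area, written independently of the package's chull-based route.
jarvis_hull_indices <- function(xy) {
  n <- nrow(xy)
  start <- order(xy[, 1], xy[, 2])[1]
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1 && n > 1) 2 else 1
    for (r in seq_len(n)) {
      if (r == p) next
      cr <- (xy[q, 1] - xy[p, 1]) * (xy[r, 2] - xy[p, 2]) -
        (xy[q, 2] - xy[p, 2]) * (xy[r, 1] - xy[p, 1])
      d_r <- sum((xy[r, ] - xy[p, ])^2)
      d_q <- sum((xy[q, ] - xy[p, ])^2)
      if (q == p || cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    p <- q
    if (p == start || length(hull) > n) break
  }
  hull
}

shoelace_oracle <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# Oracle EOO: same projection (oracled separately against geodesic areas),
# independent hull + area computation.
oracle_hull_area <- function(latitude, longitude) {
  pts <- unique(cbind(latitude, longitude))
  if (nrow(pts) < 3) return(NA_real_)
  xy <- project_equal_area(pts[, 1], pts[, 2])
  h <- jarvis_hull_indices(xy)
  shoelace_oracle(xy[h, 1], xy[h, 2])
}

# Random occurrence point sets within a Neotropical-like window.
random_points <- function(n, spread = 5) {
  lat0 <- runif(1, -30, 5)
  lon0 <- runif(1, -75, -40)
  list(latitude = lat0 + rnorm(n, sd = spread),
       longitude = lon0 + rnorm(n, sd = spread))
}

# Minimal well-formed snapshot from vectors.
toy_snapshot <- function(ids, names, lat = NA_real_, lon = NA_real_,
                         label = "toy", ...) {
  snapshot(tibble::tibble(record_id = ids, scientific_name = names,
                          latitude = lat, longitude = lon, ...),
           label = label)
}

# Strip container attributes so value-wise event comparison is exact.
event_frame <- function(events) {
  cols <- c("record_id", "major_class", "minor_class", "from_name",
            "to_name", "from_latitude", "from_longitude", "to_latitude",
            "to_longitude", "collection_year")
  df <- as.data.frame(events[cols], stringsAsFactors = FALSE)
  df <- df[do.call(order, df), ]
  rownames(df) <- NULL
  attr(df, "disappeared") <- NULL
  attr(df, "anomalies") <- NULL
  df
}
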