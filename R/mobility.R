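EARTH_RADIUS_M <- 6371000

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance in meters on a sphere of radius 6,371,000 m.
#' Vectorized over all four arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

# Centroid on the sphere: mean of unit vectors, projected back. For a pair
# of fixes this is the great-circle midpoint, so the two-point radius of
# gyration is exactly half their separation.
spherical_centroid <- function(lat, lon) {
  la <- lat * pi / 180; lo <- lon * pi / 180
  x <- mean(cos(la) * cos(lo)); y <- mean(cos(la) * sin(lo)); z <- mean(sin(la))
  c(lat = atan2(z, sqrt(x^2 + y^2)) * 180 / pi,
    lon = atan2(y, x) * 180 / pi)
}

grid_cell_keys <- function(lat, lon, cell) {
  paste(floor(lat / cell), floor(lon / cell))
}

#' Estimate the home location from GPS fixes
#'
#' Takes the modal occupied cell (heat-map cell size) among night-window
#' fixes (00:00-06:00 local), falling back to the modal all-day cell when no
#' night fix exists, and returns the centroid of the fixes in that cell.
#'
#' @param fixes GPS records (columns `timestamp,lat,lon`).
#' @param cell_deg cell size in degrees, default 0.0005 (~55 m).
#' @param night_hours half-open local-hour window treated as night.
#' @return an object of class `home_estimate` (`lat`, `lon`, `support` = fix
#'   count in the modal cell), or `NULL` when there are no fixes.
#' @export
estimate_home <- function(fixes, cell_deg = 0.0005, night_hours = c(0, 6)) {
  if (nrow(fixes) == 0L) return(NULL)
  hr <- as.POSIXlt(fixes$timestamp, tz = "UTC")$hour
  night <- fixes[hr >= night_hours[1] & hr < night_hours[2], , drop = FALSE]
  pool <- if (nrow(night)) night else fixes
  keys <- grid_cell_keys(pool$lat, pool$lon, cell_deg)
  modal <- names(which.max(table(keys)))
  members <- pool[keys == modal, , drop = FALSE]
  structure(list(lat = mean(members$lat), lon = mean(members$lon),
                 support = nrow(members)),
            class = "home_estimate")
}

#' @export
print.home_estimate <- function(x, ...) {
  cat(sprintf("<home_estimate> lat %.6f lon %.6f (support %d fixes)\n",
              x$lat, x$lon, x$support))
  invisible(x)
}

#' Radius of movement (radius of gyration)
#'
#' Root-mean-square great-circle distance of a day's fixes from their
#' spherical centroid — a dispersion measure of daily mobility. A single fix
#' has radius 0; two fixes a distance d apart have radius d/2.
#'
#' @param fixes GPS records for one day.
#' @return meters, or `NA` with zero fixes.
#' @export
radius_of_movement <- function(fixes) {
  if (nrow(fixes) == 0L) return(NA_real_)
  ctr <- spherical_centroid(fixes$lat, fixes$lon)
  d <- haversine_m(fixes$lat, fixes$lon, ctr["lat"], ctr["lon"])
  sqrt(mean(d^2))
}

#' Farthest distance traveled from home
#'
#' @param fixes GPS records for one day.
#' @param home a `home_estimate` (or list with `lat`, `lon`).
#' @return meters, or `NA` when home is unavailable or there are no fixes.
#' @export
farthest_distance_from_home <- function(fixes, home) {
  if (is.null(home) || nrow(fixes) == 0L) return(NA_real_)
  max(haversine_m(fixes$lat, fixes$lon, home$lat, home$lon))
}

#' Fraction of observed time spent outside the home
#'
#' The day is quantized to 15-minute bins; among bins containing at least
#' one fix, the fraction whose last fix lies more than `radius_m` from home.
#'
#' @param fixes GPS records for one day.
#' @param home a `home_estimate`.
#' @param radius_m home radius in meters, default 100.
#' @return fraction in `[0, 1]`, or `NA` when home is missing or no bin is
#'   observed.
#' @export
fraction_time_outside_home <- function(fixes, home, radius_m = 100) {
  if (is.null(home) || nrow(fixes) == 0L) return(NA_real_)
  fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
  idx <- bin_index(fixes$timestamp)
  last_rows <- tapply(seq_len(nrow(fixes)), idx, function(i) i[length(i)])
  last <- fixes[unlist(last_rows), , drop = FALSE]
  d <- haversine_m(last$lat, last$lon, home$lat, home$lon)
  mean(d > radius_m)
}

#' Build a heat-map count grid from GPS fixes
#'
#' Counts fixes per cell over the fixes' bounding box; the raw grid behind
#' the daily movement heat map. Total counts always equal the number of
#' fixes.
#'
#' @param fixes GPS records (at least one fix).
#' @param cell_deg cell size in degrees, default 0.0005 (~55 m).
#' @return an object of class `heatmap_grid`: list with `counts` (matrix,
#'   rows = latitude cells south to north, cols = longitude cells west to
#'   east), `lat0`, `lon0` (south-west corner), `cell_deg`, `bbox`.
#' @export
build_heatmap <- function(fixes, cell_deg = 0.0005) {
  if (nrow(fixes) == 0L) stop("cannot build a heat map from zero fixes")
  lat0 <- floor(min(fixes$lat) / cell_deg) * cell_deg
  lon0 <- floor(min(fixes$lon) / cell_deg) * cell_deg
  i <- floor((fixes$lat - lat0) / cell_deg) + 1L
  j <- floor((fixes$lon - lon0) / cell_deg) + 1L
  counts <- matrix(0L, nrow = max(i), ncol = max(j))
  for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
  structure(list(counts = counts, lat0 = lat0, lon0 = lon0,
                 cell_deg = cell_deg,
                 bbox = c(min_lat = min(fixes$lat), max_lat = max(fixes$lat),
                          min_lon = min(fixes$lon), max_lon = max(fixes$lon))),
            class = "heatmap_grid")
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat("<heatmap_grid>", nrow(x$counts), "x", ncol(x$counts), "cells of",
      x$cell_deg, "deg,", sum(x$counts), "fixes\n")
  invisible(x)
}

#' @param x a `heatmap_grid`.
#' @param ... passed to [graphics::image()].
#' @rdname build_heatmap
#' @export
plot.heatmap_grid <- function(x, ...) {
  lat_edges <- x$lat0 + (0:nrow(x$counts)) * x$cell_deg
  lon_edges <- x$lon0 + (0:ncol(x$counts)) * x$cell_deg
  graphics::image(lon_edges, lat_edges, t(x$counts),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  xlab = "longitude", ylab = "latitude", ...)
  invisible(x)
}

#' Write a heat-map grid as a tab-delimited matrix file
#'
#' @param grid a `heatmap_grid`.
#' @param path output path.
#' @export
write_heatmap <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lat0=%.6f lon0=%.6f cell_deg=%g", grid$lat0,
                     grid$lon0, grid$cell_deg), con)
  utils::write.table(grid$counts, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Daily GPS mobility features
#'
#' Bundles the day's named mobility metrics: number of fixes, radius of
#' movement, farthest distance from home, and fraction of observed
#' 15-minute bins spent outside the home.
#'
#' @param fixes GPS records for one day.
#' @param date the day's `Date`.
#' @param home a `home_estimate` (typically from the whole week's fixes).
#' @param home_radius_m radius around home counted as "at home", default 100.
#' @return one-row data frame with columns `date`, `n_fixes`,
#'   `radius_of_movement_m`, `farthest_from_home_m`, `fraction_outside_home`.
#' @export
mobility_features <- function(fixes, date, home, home_radius_m = 100) {
  data.frame(
    date = format(as.Date(date)),
    n_fixes = nrow(fixes),
    radius_of_movement_m = radius_of_movement(fixes),
    farthest_from_home_m = farthest_distance_from_home(fixes, home),
    fraction_outside_home = fraction_time_outside_home(fixes, home, home_radius_m)
  )
}
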