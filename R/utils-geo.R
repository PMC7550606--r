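# Spherical-earth geometry on lon/lat degrees. All distances use the
# conventional mean radius R = 6371 km, so 1 degree of latitude = 111.19 km.

EARTH_RADIUS_KM <- 6371

#' Great-circle distance between lon/lat points
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over rows;
#' the two inputs are recycled to a common length.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distances in kilometres.
#' @export
#' @examples
#' gc_dist_km(0, 0, 0, 1) # one degree of latitude, 111.19 km
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM)
}

#' Initial great-circle bearing
#'
#' Bearing from the first point towards the second along the great circle,
#' in degrees clockwise from true north, normalised to \[0, 360).
#'
#' @inheritParams gc_dist_km
#' @return Bearings in degrees.
#' @export
gc_bearing <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dl <- (lon2 - lon1) * r
  y <- sin(dl) * cos(lat2 * r)
  x <- cos(lat1 * r) * sin(lat2 * r) -
    sin(lat1 * r) * cos(lat2 * r) * cos(dl)
  (atan2(y, x) / r + 360) %% 360
}

# Lambert azimuthal equal-area projection about (lon0, lat0), returning
# planar km. Equal-area by construction, so polygon areas computed in the
# projected plane are areas on the sphere.
project_laea_km <- function(lon, lat, lon0, lat0) {
  rad <- pi / 180
  lam <- (lon - lon0) * rad
  phi <- lat * rad
  phi0 <- lat0 * rad
  kden <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  k <- sqrt(2 / pmax(kden, 1e-12))
  x <- EARTH_RADIUS_KM * k * cos(phi) * sin(lam)
  y <- EARTH_RADIUS_KM * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam))
  cbind(x = x, y = y)
}

# Shoelace area of a polygon given planar vertices (not necessarily closed).
shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Minimum convex polygon area of a set of positions
#'
#' Convex hull of the positions, with the area evaluated in km^2 after a
#' Lambert azimuthal equal-area projection centred on the positions'
#' centroid (raw lon/lat areas are meaningless at high latitude).
#'
#' @param lon,lat Position coordinates in decimal degrees.
#' @return Area in km^2; 0 for fewer than 3 distinct positions or a
#'   degenerate (collinear) hull.
#' @export
mcp_area_km2 <- function(lon, lat) {
  pts <- unique(cbind(lon, lat))
  if (nrow(pts) < 3) return(0)
  xy <- project_laea_km(pts[, 1], pts[, 2], mean(pts[, 1]), mean(pts[, 2]))
  h <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(h) < 3) return(0)
  shoelace_area(xy[h, 1], xy[h, 2])
}

# Cumulative along-track great-circle length, km.
track_length_km <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(0)
  sum(gc_dist_km(lon[-n], lat[-n], lon[-1], lat[-1]))
}
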