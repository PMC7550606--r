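# Synthetic environmental rasters: bathymetry, monthly SST, distance to
# coast and a land mask on a shared lon/lat grid. These stand in for the
# global relief / reconstructed-SST / coastline products a field analysis
# would download; they reproduce the semantics (units, envelopes, spatial
# structure), not any real geography.

#' Generate synthetic environmental grids
#'
#' Builds a shared lon/lat grid holding a land mask (a small archipelago
#' near the tagging origin, plus an isolated mid-ocean island when the
#' domain reaches it), distance to the nearest coast (great-circle km),
#' a shelf-slope-basin bathymetry driven by coast distance, and monthly
#' sea-surface temperature decreasing with latitude, clamped to the
#' -1.8 to 19.3 degC envelope.
#'
#' @param lon_range,lat_range Length-2 domain bounds in degrees.
#' @param resolution Grid spacing in degrees.
#' @param archipelago Length-2 centre `c(lon, lat)` of the land mass near
#'   the track origin.
#' @param seed Integer seed for the smooth bathymetric noise field.
#' @return An object of class `env_grids`: list with `lon`, `lat` axis
#'   vectors, matrices `depth` (m, positive down, `NA` on land),
#'   `coast_dist` (km, 0 on land), logical `land_mask`, and `sst` an
#'   `nlon x nlat x 12` array (degC per calendar month).
#' @export
generate_env_grids <- function(lon_range = c(-30, 20),
                               lat_range = c(30, 82),
                               resolution = 0.5,
                               archipelago = c(14, 78.5),
                               seed = 1L) {
  if (diff(lon_range) <= 0 || diff(lat_range) <= 0 || resolution <= 0)
    stop("degenerate domain or non-positive resolution")
  set.seed(seed)
  lon <- seq(lon_range[1], lon_range[2], by = resolution)
  lat <- seq(lat_range[1], lat_range[2], by = resolution)
  nx <- length(lon); ny <- length(lat)
  LON <- matrix(lon, nx, ny)
  LAT <- matrix(lat, nx, ny, byrow = TRUE)

  # archipelago: an irregular blob in plain degree units, elongated along
  # the meridian like a high-Arctic island group (~1.5 deg lon x 2 deg lat)
  dx <- LON - archipelago[1]
  dy <- LAT - archipelago[2]
  land <- (dx / 1.5)^2 + (dy / 2.0)^2 +
    0.35 * sin(3 * atan2(dy, dx)) < 1
  # a small isolated island far down-track (Jan Mayen analogue)
  if (min(lon) < -8 && min(lat) < 71.2) {
    dx2 <- LON + 8.5
    dy2 <- LAT - 71
    land <- land | (dx2^2 + (dy2 * 2)^2 < 0.6^2)
  }

  coast <- coast_distance_km(lon, lat, land)

  # shelf-slope-basin: depth grows with distance from the coast, with a
  # smooth low-frequency undulation; 2 m minimum at sea, basin ~5.4 km
  und <- 350 * sin(LON / 7 + runif(1, 0, 2 * pi)) *
    cos(LAT / 5 + runif(1, 0, 2 * pi))
  depth <- 60 + 5200 * (1 - exp(-coast / 250)) + und
  depth <- pmin(pmax(depth, 2), 5500)
  depth[land] <- NA_real_

  # SST: linear latitude gradient plus a seasonal cycle peaking in early
  # September, clamped to the observed envelope
  sst <- array(NA_real_, c(nx, ny, 12))
  for (m in 1:12) {
    seasonal <- 3.2 * cos(2 * pi * (m - 8.6) / 12)
    field <- 27 - 0.38 * LAT + seasonal + 0.02 * LON
    field <- pmin(pmax(field, -1.8), 19.3)
    field[land] <- NA_real_
    sst[, , m] <- field
  }

  structure(list(lon = lon, lat = lat, depth = depth, sst = sst,
                 coast_dist = coast, land_mask = land),
            class = "env_grids")
}

# exact nearest-land-cell great-circle distance for every cell; 0 on land
coast_distance_km <- function(lon, lat, land) {
  nx <- length(lon); ny <- length(lat)
  out <- matrix(Inf, nx, ny)
  out[land] <- 0
  idx <- which(land, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out) # no land anywhere: infinite coast dist
  land_pts <- cbind(lon[idx[, 1]], lat[idx[, 2]])
  sea <- which(!land, arr.ind = TRUE)
  for (k in seq_len(nrow(land_pts))) {
    d <- geosphere::distHaversine(land_pts[k, ],
                                  cbind(lon[sea[, 1]], lat[sea[, 2]]),
                                  r = EARTH_RADIUS_KM)
    out[sea] <- pmin(out[sea], d)
  }
  out
}

#' @export
print.env_grids <- function(x, ...) {
  cat(sprintf(
    "<env_grids> %d x %d cells, lon [%g, %g], lat [%g, %g]\n",
    length(x$lon), length(x$lat), min(x$lon), max(x$lon),
    min(x$lat), max(x$lat)))
  cat(sprintf("  land cells: %d; depth %g-%g m; SST %g-%g degC\n",
              sum(x$land_mask), min(x$depth, na.rm = TRUE),
              max(x$depth, na.rm = TRUE), min(x$sst, na.rm = TRUE),
              max(x$sst, na.rm = TRUE)))
  invisible(x)
}

env_cell_index <- function(env, lon, lat) {
  i <- round((lon - env$lon[1]) / (env$lon[2] - env$lon[1])) + 1
  j <- round((lat - env$lat[1]) / (env$lat[2] - env$lat[1])) + 1
  if (any(i < 1 | i > length(env$lon) | j < 1 | j > length(env$lat),
          na.rm = TRUE))
    stop("locations fall outside the environmental grid domain")
  cbind(i, j)
}

env_is_land <- function(env, lon, lat) {
  i <- round((lon - env$lon[1]) / (env$lon[2] - env$lon[1])) + 1
  j <- round((lat - env$lat[1]) / (env$lat[2] - env$lat[1])) + 1
  bad <- i < 1 | i > length(env$lon) | j < 1 | j > length(env$lat)
  i <- pmin(pmax(i, 1), length(env$lon))
  j <- pmin(pmax(j, 1), length(env$lat))
  out <- env$land_mask[cbind(i, j)]
  out[bad] <- FALSE # outside the grid counts as open ocean
  out
}

#' Convert environmental grids to a long tibble
#'
#' One row per ocean or land cell with depth, coast distance, land flag and
#' the requested month's SST — convenient for ggplot2 rasters.
#'
#' @param env An `env_grids` object.
#' @param month Calendar month (1-12) whose SST layer to attach.
#' @return A tibble with columns `lon`, `lat`, `depth`, `sst`,
#'   `coast_dist`, `land`.
#' @export
env_as_tibble <- function(env, month = 9) {
  # expand_grid(lat, lon) cycles lon fastest, matching column-major
  # as.vector() on the nlon x nlat matrices
  grid <- tidyr::expand_grid(lat = env$lat, lon = env$lon)
  grid$depth <- as.vector(env$depth)
  grid$sst <- as.vector(env$sst[, , month])
  grid$coast_dist <- as.vector(env$coast_dist)
  grid$land <- as.vector(env$land_mask)
  dplyr::relocate(grid, "lon", "lat")
}
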