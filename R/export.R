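# Plain-text exports: environmental grids as long CSV and ARS-patch
# minimum convex polygons as GeoJSON.

#' Write environmental grids to a long-format CSV
#'
#' One row per cell with `lon`, `lat`, `depth`, `coast_dist`, `land`
#' and one `sst_01` ... `sst_12` column per calendar month — a
#' plain-text equivalent of a NetCDF raster stack.
#'
#' @param env An [generate_env_grids()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_env_csv <- function(env, path) {
  tb <- env_as_tibble(env, month = 1)
  tb$sst <- NULL
  for (m in 1:12)
    tb[[sprintf("sst_%02d", m)]] <- as.vector(env$sst[, , m])
  utils::write.csv(as.data.frame(tb), path, row.names = FALSE)
  invisible(path)
}

#' Read environmental grids from the long CSV written by [write_env_csv()]
#'
#' @param path CSV path.
#' @return An `env_grids` object.
#' @export
read_env_csv <- function(path) {
  tb <- utils::read.csv(path)
  lon <- sort(unique(tb$lon)); lat <- sort(unique(tb$lat))
  nx <- length(lon); ny <- length(lat)
  ix <- match(tb$lon, lon); iy <- match(tb$lat, lat)
  put <- function(v) {
    m <- matrix(NA_real_, nx, ny)
    m[cbind(ix, iy)] <- v
    m
  }
  sst <- array(NA_real_, c(nx, ny, 12))
  for (m in 1:12) sst[, , m] <- put(tb[[sprintf("sst_%02d", m)]])
  land <- put(as.numeric(tb$land)) > 0
  structure(list(lon = lon, lat = lat, depth = put(tb$depth), sst = sst,
                 coast_dist = put(tb$coast_dist), land_mask = land),
            class = "env_grids")
}

#' Write ARS-patch convex polygons as GeoJSON
#'
#' Each patch becomes one Feature: a Polygon tracing the convex hull of
#' its member locations (lon/lat, closed ring) with the patch metrics as
#' properties. Degenerate patches (fewer than 3 distinct positions) are
#' written as Point features.
#'
#' @param phases Metric-filled phase tibble (see [phase_metrics()]).
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_phases_geojson <- function(phases, path) {
  features <- purrr::map(seq_len(nrow(phases)), function(i) {
    rows <- phases$rows[[i]]
    pts <- unique(cbind(rows$lon, rows$lat))
    geom <- if (nrow(pts) >= 3) {
      h <- grDevices::chull(pts[, 1], pts[, 2])
      ring <- pts[c(h, h[1]), , drop = FALSE]
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)), function(r)
             c(ring[r, 1], ring[r, 2]))))
    } else {
      list(type = "Point", coordinates = c(pts[1, 1], pts[1, 2]))
    }
    props <- as.list(dplyr::select(phases[i, ], -"rows"))
    props$start_time <- format(props$start_time, "%Y-%m-%dT%H:%M:%SZ")
    props$end_time <- format(props$end_time, "%Y-%m-%dT%H:%M:%SZ")
    list(type = "Feature", geometry = geom, properties = props)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
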