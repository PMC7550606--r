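# Reading, validating, filtering and segmenting raw Argos location tables.

LC_LEVELS <- c("3", "2", "1", "0", "A", "B", "Z")

#' Read a raw Argos location CSV
#'
#' Expects columns `id`, `timestamp` (ISO-8601 UTC), `lon`, `lat`, `lc`
#' (location class 3, 2, 1, 0, A, B or Z); alternative export headers can
#' be mapped via `col_map`. Rows are sorted by (id, timestamp),
#' exact duplicates are dropped, unusable Z-class fixes are removed by
#' default, and rows with the same id and timestamp are resolved by
#' keeping the better location class (3 > 2 > 1 > 0 > A > B), then
#' first-seen. Malformed rows (unparseable timestamp or coordinates, or
#' latitude outside \[-90, 90\]) are dropped with a warning naming their
#' line numbers.
#'
#' @param path CSV file path.
#' @param drop_z Remove Z-class rows (default `TRUE`).
#' @param col_map Named character vector mapping the required names to the
#'   file's actual column names, e.g.
#'   `c(timestamp = "Date", lc = "Quality")`.
#' @return A tibble of raw locations sorted by id and time, with `lon`
#'   normalised to \[-180, 180\]. Attributes `n_read`, `n_z_removed`,
#'   `n_dup_removed` record the filtering bookkeeping.
#' @export
read_argos_csv <- function(path, drop_z = TRUE, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(raw))
        stop("mapped column not in file: ", col_map[[nm]])
      names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  needed <- c("id", "timestamp", "lon", "lat", "lc")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  tidy_argos(tibble::as_tibble(raw[needed]), drop_z = drop_z)
}

#' Validate and filter an in-memory Argos location table
#'
#' The same cleaning as [read_argos_csv()] applied to a data frame that is
#' already in memory (e.g. straight from [generate_fleet()]).
#'
#' @param locations Data frame with columns `id`, `timestamp`, `lon`,
#'   `lat`, `lc`.
#' @inheritParams read_argos_csv
#' @return See [read_argos_csv()].
#' @export
tidy_argos <- function(locations, drop_z = TRUE) {
  x <- tibble::as_tibble(locations)
  n_read <- nrow(x)
  if (!inherits(x$timestamp, "POSIXct"))
    x$timestamp <- parse_timestamps(as.character(x$timestamp))
  x$lon <- suppressWarnings(as.numeric(x$lon))
  x$lat <- suppressWarnings(as.numeric(x$lat))
  x$lc <- as.character(x$lc)
  bad <- is.na(x$timestamp) | is.na(x$lon) | is.na(x$lat) |
    !x$lc %in% LC_LEVELS | x$lat < -90 | x$lat > 90
  if (any(bad))
    warning(sum(bad), " malformed row(s) dropped (lines ",
            paste(utils::head(which(bad), 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", ")")
  x <- x[!bad, , drop = FALSE]
  x$lon <- ((x$lon + 180) %% 360) - 180

  x <- dplyr::distinct(x) # exact duplicates
  n_z <- if (drop_z) sum(x$lc == "Z") else 0L
  if (drop_z) x <- dplyr::filter(x, .data$lc != "Z")

  # same id+timestamp: keep the better class, then first-seen
  x <- x |>
    dplyr::mutate(.rank = match(.data$lc, LC_LEVELS)) |>
    dplyr::arrange(.data$id, .data$timestamp, .data$.rank) |>
    dplyr::distinct(.data$id, .data$timestamp, .keep_all = TRUE) |>
    dplyr::select(-".rank")
  n_dup <- n_read - n_z - nrow(x) - sum(bad)

  attr(x, "n_read") <- n_read
  attr(x, "n_z_removed") <- n_z
  attr(x, "n_dup_removed") <- n_dup
  x
}

# per-row tolerant parsing: each row keeps the first format that fits
parse_timestamps <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_character_), tz = "UTC")[rep(1, length(x))]
  for (f in fmts) {
    need <- which(is.na(out))
    if (length(need) == 0) break
    out[need] <- as.POSIXct(strptime(x[need], format = f, tz = "UTC"))
  }
  out
}

#' Split tracks at long transmission gaps and drop short segments
#'
#' Within each individual, the track is split wherever the interval
#' between consecutive locations exceeds `gap_days` (strictly; a gap of
#' exactly `gap_days` does not split), and resulting segments spanning
#' less than `min_days` of elapsed time are removed (a span of exactly
#' `min_days` is kept).
#'
#' @param locations Tibble of cleaned locations
#'   (see [tidy_argos()]); may hold many individuals.
#' @param gap_days Split threshold in days.
#' @param min_days Minimum retained segment span in days.
#' @return The input rows that survive, with a `segment` column
#'   (`"<id>_seg<k>"` ordinal within individual). Attribute
#'   `n_short_dropped` counts removed rows.
#' @export
filter_and_split <- function(locations, gap_days = 4, min_days = 3) {
  if (nrow(locations) == 0) {
    out <- dplyr::mutate(tibble::as_tibble(locations),
                         segment = character(0))
    attr(out, "n_short_dropped") <- 0L
    return(out)
  }
  out <- locations |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$id, .data$timestamp) |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(
      .gap_d = c(0, diff(as.numeric(.data$timestamp))) / 86400,
      .seg = cumsum(.data$.gap_d > gap_days),
      segment = sprintf("%s_seg%d", .data$id, .data$.seg + 1L)) |>
    dplyr::ungroup() |>
    dplyr::select(-".gap_d", -".seg")
  spans <- out |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(span_d = diff(range(as.numeric(.data$timestamp))) / 86400)
  keep <- spans$segment[spans$span_d >= min_days]
  dropped <- sum(!out$segment %in% keep)
  out <- dplyr::filter(out, .data$segment %in% keep)
  attr(out, "n_short_dropped") <- dropped
  out
}

#' Summarise a location table
#'
#' Per-individual counts, great-circle step distances (km, radius
#' 6371 km), inter-location intervals (h) and the location-class
#' frequency table.
#'
#' @param locations Tibble of cleaned locations.
#' @return A tibble with one row per individual: `n`, mean/min/max of
#'   step distance and interval (`NA` when fewer than 2 locations), and
#'   one `n_<class>` count column per observed class.
#' @export
track_summary <- function(locations) {
  base <- locations |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$id, .data$timestamp) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n = dplyr::n(),
      dist_mean_km = mean_or_na(step_dists(.data$lon, .data$lat)),
      dist_min_km = min_or_na(step_dists(.data$lon, .data$lat)),
      dist_max_km = max_or_na(step_dists(.data$lon, .data$lat)),
      dur_mean_h = mean_or_na(diff(as.numeric(.data$timestamp)) / 3600),
      dur_min_h = min_or_na(diff(as.numeric(.data$timestamp)) / 3600),
      dur_max_h = max_or_na(diff(as.numeric(.data$timestamp)) / 3600))
  classes <- locations |>
    dplyr::count(.data$id, .data$lc) |>
    tidyr::pivot_wider(names_from = "lc", values_from = "n",
                       names_prefix = "n_", values_fill = 0L)
  dplyr::left_join(base, classes, by = "id")
}

step_dists <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(numeric(0))
  gc_dist_km(lon[-n], lat[-n], lon[-1], lat[-1])
}
mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
min_or_na <- function(x) if (length(x)) min(x) else NA_real_
max_or_na <- function(x) if (length(x)) max(x) else NA_real_

#' Write a location table as CSV
#'
#' Timestamps are serialised as ISO-8601 UTC so that
#' `read_argos_csv(write_argos_csv(x))` round-trips.
#'
#' @param locations Location tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_argos_csv <- function(locations, path) {
  out <- as.data.frame(locations)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
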