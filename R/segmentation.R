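# Rule-based segmentation of classified tracks: departure from the
# residency region, Kaplan-Meier residency, ARS patches and migratory
# phases, patch metrics, and monthly dispersion bearings.

#' Detect departure from the residency region
#'
#' Departure is the start of the first run of consecutive grid locations
#' that are all classified as transiting AND all further than
#' `min_coast_km` from the coast, spanning at least `min_hours` (strictly
#' less than `min_hours` does not qualify). Runs must be contiguous on the
#' regular grid: a time gap larger than the grid step (e.g. where land
#' locations were removed) breaks the run. Individuals with no such run
#' are censored at their last transmission.
#'
#' @param series Classified state-series tibble for one individual, with
#'   a `coast_dist` column (km) attached (see [extract_environment()]).
#' @param min_hours Minimum duration of the qualifying run, hours.
#' @param min_coast_km Minimum distance from the coast, km.
#' @param time_step_h Grid spacing used to test contiguity, hours.
#' @return A one-row tibble: `id`, `departed`, `departure_time`,
#'   `censor_time`.
#' @export
detect_departure <- function(series, min_hours = 48, min_coast_km = 150,
                             time_step_h = 2) {
  if (!"coast_dist" %in% names(series))
    stop("series must carry a coast_dist column; run extract_environment()")
  s <- dplyr::arrange(series, .data$time)
  ok <- s$b_class == "transit" & s$coast_dist > min_coast_km
  contig <- c(TRUE, diff(as.numeric(s$time)) <= time_step_h * 3600 + 1)
  run_id <- cumsum(!ok | !contig)
  dep_time <- as.POSIXct(NA, tz = "UTC")
  for (r in unique(run_id[ok])) {
    rows <- which(run_id == r & ok)
    if (length(rows) < 2) next
    span_h <- diff(range(as.numeric(s$time[rows]))) / 3600
    if (span_h >= min_hours) {
      dep_time <- s$time[rows[1]]
      break
    }
  }
  tibble::tibble(
    id = s$id[1],
    departed = !is.na(dep_time),
    departure_time = dep_time,
    censor_time = s$time[nrow(s)])
}

#' Kaplan-Meier residency curve
#'
#' Product-limit estimate of the probability of not yet having departed,
#' as a function of days since `origin_date`; tags that stopped before a
#' departure was identified enter as right-censored. Fitted with
#' [survival::survfit()].
#'
#' @param outcomes Tibble of departure outcomes, one row per individual
#'   (see [detect_departure()]).
#' @param origin_date Day-0 origin (default 10 September of the
#'   deployment year — the first-deployment convention).
#' @return A tibble of class `residency_curve` with columns `time` (days
#'   since origin), `survival`, `lower`, `upper` (25%/75% band: the
#'   survival quartile envelope from the product-limit CI), `n_risk`,
#'   `n_event`; attributes `median_departure_day` and
#'   `median_departure_date` (NA if the curve never reaches 0.5).
#' @export
kaplan_meier_residency <- function(outcomes,
                                   origin_date = NULL) {
  stopifnot(nrow(outcomes) >= 1)
  end_time <- dplyr::coalesce(outcomes$departure_time,
                              outcomes$censor_time)
  if (is.null(origin_date)) {
    yr <- as.integer(format(min(end_time), "%Y"))
    origin_date <- as.POSIXct(sprintf("%d-09-10 00:00:00", yr),
                              tz = "UTC")
  }
  days <- as.numeric(end_time - origin_date, units = "days")
  fit <- survival::survfit(
    survival::Surv(days, outcomes$departed) ~ 1,
    conf.int = 0.50, conf.type = "log-log")
  sf <- summary(fit, censored = TRUE)
  out <- tibble::tibble(
    time = sf$time, survival = sf$surv,
    lower = sf$lower, upper = sf$upper,
    n_risk = sf$n.risk, n_event = sf$n.event)
  med <- out$time[which(out$survival <= 0.5)[1]]
  attr(out, "median_departure_day") <- med
  attr(out, "median_departure_date") <-
    if (!is.na(med)) origin_date + med * 86400 else as.POSIXct(NA)
  attr(out, "origin_date") <- origin_date
  class(out) <- c("residency_curve", class(out))
  out
}

#' Identify ARS patches and migratory phases
#'
#' A migratory phase begins after 3 or more successive locations with
#' posterior-mean state below the lower cutoff (transiting) and ends at
#' the location before the first run of 3 or more consecutive locations
#' at or above it. An ARS patch begins after 3 or more successive
#' locations above the upper cutoff and ends before the first run of 3 or
#' more consecutive locations at or below it. The two rules are applied
#' independently; short (< 3) interruptions stay inside a phase, and
#' trailing non-qualifying locations at track end are trimmed.
#'
#' @param series Classified state-series tibble for one individual (or
#'   one segment), time-ordered.
#' @param cutoffs Length-2 cutoff vector, default `c(1.25, 1.75)`.
#' @param min_run Run length that starts/ends a phase (3 by convention).
#' @return A tibble with one row per phase: `id`, `kind` (`"ARS"` or
#'   `"migratory"`), `start_time`, `end_time`, `duration_days`, `n_locs`,
#'   and a `rows` list-column holding the member grid rows.
#' @export
identify_phases <- function(series, cutoffs = c(1.25, 1.75),
                            min_run = 3) {
  s <- dplyr::arrange(series, .data$time)
  ars <- phase_runs(s$b_mean > cutoffs[2], min_run)
  mig <- phase_runs(s$b_mean < cutoffs[1], min_run)
  build <- function(idx, kind) {
    if (length(idx) == 0) return(NULL)
    purrr::map_dfr(idx, function(rg) {
      rows <- s[rg[1]:rg[2], , drop = FALSE]
      tibble::tibble(
        id = s$id[1], kind = kind,
        start_time = rows$time[1],
        end_time = rows$time[nrow(rows)],
        duration_days = as.numeric(rows$time[nrow(rows)] - rows$time[1],
                                   units = "days"),
        n_locs = nrow(rows),
        rows = list(rows))
    })
  }
  out <- dplyr::bind_rows(build(ars, "ARS"), build(mig, "migratory"))
  if (nrow(out) == 0)
    return(tibble::tibble(id = character(0), kind = character(0),
                          start_time = s$time[0], end_time = s$time[0],
                          duration_days = numeric(0),
                          n_locs = integer(0), rows = list()))
  dplyr::arrange(out, .data$start_time)
}

# index ranges [start, end] of phases of one kind given the qualifying
# indicator; a phase starts at the first of >= min_run consecutive TRUE
# and ends before the first of >= min_run consecutive FALSE, trimmed back
# to the last TRUE member
phase_runs <- function(qual, min_run) {
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  phases <- list()
  open <- NA_integer_
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] >= min_run && is.na(open))
      open <- starts[k]
    if (!r$values[k] && r$lengths[k] >= min_run && !is.na(open)) {
      phases[[length(phases) + 1]] <- c(open, starts[k] - 1)
      open <- NA_integer_
    }
  }
  if (!is.na(open)) {
    # trim trailing non-qualifying rows at track end
    last_true <- max(which(qual))
    phases[[length(phases) + 1]] <- c(open, last_true)
  }
  phases
}

#' Fill movement and habitat metrics for identified phases
#'
#' For each phase: duration in days, mean horizontal speed (sum of
#' consecutive great-circle distances over elapsed time, km/h), minimum
#' convex polygon area (km^2, equal-area projection about the patch
#' centroid; 0 and flagged when fewer than 3 distinct positions), mean
#' depth and month-matched mean SST over member locations, and the start
#' day relative to the 10 September day-0 convention.
#'
#' @param phases Output of [identify_phases()].
#' @param env An [generate_env_grids()] object (optional; without it the
#'   environmental means are `NA`).
#' @param origin_date Day-0 origin; default 10 September of the phase's
#'   deployment season (the most recent 10 September at or before the
#'   phase start).
#' @return `phases` with columns `mcp_area_km2`, `mean_speed_kmh`,
#'   `total_dist_km`, `mean_depth_m`, `mean_sst_c`, `start_day`,
#'   `degenerate_mcp` added.
#' @export
phase_metrics <- function(phases, env = NULL, origin_date = NULL) {
  if (nrow(phases) == 0) return(phases)
  met <- purrr::map_dfr(phases$rows, function(rows) {
    dist <- track_length_km(rows$lon, rows$lat)
    span_h <- diff(range(as.numeric(rows$time))) / 3600
    area <- mcp_area_km2(rows$lon, rows$lat)
    n_distinct_pos <- nrow(unique(cbind(rows$lon, rows$lat)))
    if (is.null(env)) {
      depth <- sst <- NA_real_
    } else {
      ex <- extract_environment(rows, env)
      depth <- mean(ex$depth, na.rm = TRUE)
      sst <- mean(ex$sst, na.rm = TRUE)
    }
    org <- origin_date
    if (is.null(org)) {
      yr <- as.integer(format(rows$time[1], "%Y"))
      org <- as.POSIXct(sprintf("%d-09-10 00:00:00", yr), tz = "UTC")
      if (org > rows$time[1]) org <- as.POSIXct(
        sprintf("%d-09-10 00:00:00", yr - 1), tz = "UTC")
    }
    tibble::tibble(
      mcp_area_km2 = area,
      mean_speed_kmh = if (span_h > 0) dist / span_h else 0,
      total_dist_km = dist,
      mean_depth_m = depth,
      mean_sst_c = sst,
      start_day = as.numeric(rows$time[1] - org, units = "days"),
      degenerate_mcp = n_distinct_pos < 3 || area == 0)
  })
  dplyr::bind_cols(phases, met)
}

#' Monthly dispersion bearings from the departure location
#'
#' For each calendar month with locations after departure, the initial
#' great-circle bearing from the departure location to the last position
#' in that month, in degrees clockwise from true north.
#'
#' @param series Classified state-series tibble for one individual.
#' @param departure The individual's [detect_departure()] row.
#' @return Tibble `id`, `month` (1-12), `year`, `bearing_deg`; zero rows
#'   for non-departed individuals.
#' @export
monthly_dispersion_bearings <- function(series, departure) {
  if (!isTRUE(departure$departed[1]))
    return(tibble::tibble(id = character(0), month = integer(0),
                          year = integer(0), bearing_deg = numeric(0)))
  dep_t <- departure$departure_time[1]
  s <- dplyr::filter(dplyr::arrange(series, .data$time),
                     .data$time >= dep_t)
  dep_row <- s[1, ]
  s |>
    dplyr::mutate(month = as.integer(format(.data$time, "%m")),
                  year = as.integer(format(.data$time, "%Y"))) |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      id = .data$id, month = .data$month, year = .data$year,
      bearing_deg = gc_bearing(dep_row$lon, dep_row$lat,
                               .data$lon, .data$lat))
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of bearings is directed. Returns the mean
#' resultant length `R_bar` and the standard finite-sample approximation
#' to the p-value, `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`
#' with `R = n * R_bar`.
#'
#' @param bearings_deg Bearings in degrees (at least 2).
#' @return A one-row tibble: `n`, `r_bar`, `mean_bearing_deg`, `p_value`.
#' @export
#' @examples
#' rayleigh_test(c(210, 215, 220, 225, 218))
rayleigh_test <- function(bearings_deg) {
  n <- length(bearings_deg)
  if (n < 2) stop("need at least 2 bearings")
  rad <- bearings_deg * pi / 180
  cbar <- mean(cos(rad)); sbar <- mean(sin(rad))
  r_bar <- sqrt(cbar^2 + sbar^2)
  R <- n * r_bar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  tibble::tibble(
    n = n, r_bar = r_bar,
    mean_bearing_deg = (atan2(sbar, cbar) * 180 / pi + 360) %% 360,
    p_value = min(max(p, 0), 1))
}
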