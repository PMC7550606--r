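test_that("departure needs 48 h of offshore transiting", {
  # 50 h of transit at 200 km offshore: departs at the run start
  s <- make_series(c(rep(1.9, 5), rep(1.1, 26), rep(1.9, 3)),
                   coast_dist = rep(200, 34))
  d <- detect_departure(s)
  expect_true(d$departed)
  expect_equal(d$departure_time, s$time[6])

  # 72 h of transit but only 100 km offshore: no departure
  s2 <- make_series(rep(1.1, 37), coast_dist = rep(100, 37))
  d2 <- detect_departure(s2)
  expect_false(d2$departed)
  expect_equal(d2$censor_time, s2$time[37])

  # a 46-h offshore transit run (< 48) then ARS: no departure
  s3 <- make_series(c(rep(1.1, 24), rep(1.9, 10)),
                    coast_dist = rep(200, 34))
  expect_false(detect_departure(s3)$departed)
  # exactly 48 h qualifies
  s4 <- make_series(c(rep(1.1, 25), rep(1.9, 10)),
                    coast_dist = rep(200, 35))
  expect_true(detect_departure(s4)$departed)

  expect_error(detect_departure(dplyr::select(s, -coast_dist)),
               "coast_dist")
})

test_that("departure is monotone in its thresholds", {
  set.seed(7)
  b <- 1 + (runif(300) < 0.4) * 0.9
  coast <- 120 + cumsum(rnorm(300, 1, 10))
  s <- make_series(b, coast_dist = pmax(coast, 0))
  base <- detect_departure(s)
  expect_type(base$departed, "logical")
  for (km in c(160, 200)) {
    d <- detect_departure(s, min_coast_km = km)
    if (d$departed && base$departed)
      expect_gte(as.numeric(d$departure_time),
                 as.numeric(base$departure_time))
  }
  for (h in c(60, 72)) {
    d <- detect_departure(s, min_hours = h)
    if (d$departed && base$departed)
      expect_gte(as.numeric(d$departure_time),
                 as.numeric(base$departure_time))
  }
})

test_that("gaps in the regular grid break a qualifying run", {
  s <- make_series(rep(1.1, 30), coast_dist = rep(200, 30))
  s$time[16:30] <- s$time[16:30] + 12 * 3600 # 12-h hole mid-run
  d <- detect_departure(s)
  expect_false(d$departed) # neither half spans 48 h
})

outcome_row <- function(id, dep_day, censor_day,
                        origin = as.POSIXct("2019-09-10", tz = "UTC")) {
  tibble::tibble(
    id = id, departed = !is.na(dep_day),
    departure_time = origin + ifelse(is.na(dep_day), NA, dep_day) * 86400,
    censor_time = origin + censor_day * 86400)
}

test_that("Kaplan-Meier curve matches the hand product-limit estimate", {
  origin <- as.POSIXct("2019-09-10", tz = "UTC")
  oc <- dplyr::bind_rows(
    outcome_row("a", 3, 3), outcome_row("b", 5, 5),
    outcome_row("c", 7, 7), outcome_row("d", 9, 9))
  km <- kaplan_meier_residency(oc, origin)
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(attr(km, "median_departure_day"), 5)

  # mixed events and censoring vs the brute-force oracle
  oc2 <- dplyr::bind_rows(
    outcome_row("a", 2, 2), outcome_row("b", NA, 3),
    outcome_row("c", 4, 4))
  km2 <- kaplan_meier_residency(oc2, origin)
  or <- km_oracle(c(2, 3, 4), c(TRUE, FALSE, TRUE))
  got <- km2[km2$n_event > 0, ]
  expect_equal(got$survival, or$surv, tolerance = 1e-12)

  # all censored: survival stays 1, no median
  oc3 <- dplyr::bind_rows(outcome_row("a", NA, 5),
                          outcome_row("b", NA, 8))
  km3 <- kaplan_meier_residency(oc3, origin)
  expect_true(all(km3$survival == 1))
  expect_true(is.na(attr(km3, "median_departure_day")))
  # survival is non-increasing and in [0, 1] in every case
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
})

test_that("K-M equals the empirical survival function without censoring", {
  origin <- as.POSIXct("2019-09-10", tz = "UTC")
  days <- c(2, 2, 5, 6, 11)
  oc <- dplyr::bind_rows(lapply(seq_along(days), function(i)
    outcome_row(letters[i], days[i], days[i])))
  km <- kaplan_meier_residency(oc, origin)
  ev <- km[km$n_event > 0, ]
  emp <- sapply(ev$time, function(t) mean(days > t))
  expect_equal(ev$survival, emp, tolerance = 1e-12)
})

test_that("phase identification applies the 3-consecutive rules", {
  s <- make_series(c(rep(1.9, 5), rep(1.5, 3), rep(1.9, 4)))
  ph <- identify_phases(s)
  ars <- ph[ph$kind == "ARS", ]
  expect_equal(nrow(ars), 2)
  expect_equal(ars$n_locs, c(5, 4)) # ends before the three 1.5 values
  expect_equal(ars$start_time[2], s$time[9])

  # only 2 successive ARS locations: no patch starts
  ph2 <- identify_phases(make_series(c(1.9, 1.9, 1.5, 1.5, 1.5, 1.5)))
  expect_equal(sum(ph2$kind == "ARS"), 0)

  # all transit: one migratory phase, no ARS patch
  ph3 <- identify_phases(make_series(rep(1.1, 10)))
  expect_equal(nrow(ph3), 1)
  expect_equal(ph3$kind, "migratory")
  expect_equal(ph3$n_locs, 10)

  # short interruptions stay inside the phase
  s4 <- make_series(c(rep(1.9, 4), 1.5, 1.5, rep(1.9, 4)))
  ph4 <- identify_phases(s4)
  expect_equal(nrow(ph4[ph4$kind == "ARS", ]), 1)
  expect_equal(ph4$n_locs[ph4$kind == "ARS"], 10)
})

test_that("phases of one kind are disjoint and time-ordered", {
  set.seed(11)
  b <- 1 + (runif(400) < 0.5) * runif(400)
  s <- make_series(pmin(b, 2))
  ph <- identify_phases(s)
  for (kind in c("ARS", "migratory")) {
    rows <- ph[ph$kind == kind, ]
    if (nrow(rows) < 2) next
    idx <- lapply(rows$rows, function(r) as.numeric(r$time))
    for (i in seq_len(nrow(rows) - 1))
      expect_lt(max(idx[[i]]), min(idx[[i + 1]]))
  }
  # member rows are contiguous grid runs
  for (r in ph$rows)
    expect_true(all(diff(as.numeric(r$time)) == 7200))
})

test_that("patch metrics: MCP area, speed and distance arithmetic", {
  # 1 deg x 1 deg square at the equator, area ~ (111.195 km)^2
  sq <- make_series(rep(1.9, 4), lon = c(0, 1, 1, 0),
                    lat = c(0, 0, 1, 1))
  ph <- phase_metrics(identify_phases(sq))
  oracle <- suppressWarnings(geosphere::areaPolygon(
    cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), r = 6371000)) / 1e6
  expect_equal(ph$mcp_area_km2, oracle, tolerance = 0.005 * oracle)
  expect_equal(ph$mcp_area_km2, 111.195^2, tolerance = 0.005 * 111.195^2)

  # MCP area is invariant to point order and duplication
  expect_equal(mcp_area_km2(c(1, 0, 1, 0, 0), c(0, 1, 1, 0, 1)),
               ph$mcp_area_km2[1])

  # stationary phase: zero speed and area, flagged degenerate
  st <- make_series(rep(1.9, 5), lon = rep(3, 5), lat = rep(60, 5))
  phs <- phase_metrics(identify_phases(st))
  expect_equal(phs$mean_speed_kmh, 0)
  expect_equal(phs$mcp_area_km2, 0)
  expect_true(phs$degenerate_mcp)
})

test_that("a week at 9.3 km/h covers 223.2 km per day", {
  step_km <- 9.3 * 2
  dlat <- step_km / 111.19493
  n <- 12 * 7 + 1 # 7 days of 2-h steps
  s <- make_series(rep(1.0, n), lon = rep(0, n),
                   lat = 70 - (0:(n - 1)) * dlat)
  ph <- phase_metrics(identify_phases(s))
  expect_equal(ph$kind, "migratory")
  expect_equal(ph$mean_speed_kmh, 9.3, tolerance = 1e-3)
  expect_equal(ph$mean_speed_kmh * 24, 223.2, tolerance = 0.05)
  expect_equal(ph$duration_days, 7)
  expect_gt(ph$total_dist_km, 1500)
})

test_that("monthly dispersion bearings point where they should", {
  dep <- tibble::tibble(id = "w1", departed = TRUE,
                        departure_time = as.POSIXct("2019-09-25",
                                                    tz = "UTC"),
                        censor_time = as.POSIXct("2019-11-30",
                                                 tz = "UTC"))
  # due south along a meridian
  s <- make_series(rep(1.1, 40), lon = rep(10, 40),
                   lat = 78 - (0:39) * 0.1,
                   t0 = as.POSIXct("2019-09-25", tz = "UTC"))
  b <- monthly_dispersion_bearings(s, dep)
  expect_equal(b$bearing_deg, rep(180, nrow(b)), tolerance = 1e-9)

  # due east on the equator
  s2 <- make_series(rep(1.1, 10), lon = 0 + (0:9) * 0.5,
                    lat = rep(0, 10),
                    t0 = as.POSIXct("2019-09-25", tz = "UTC"))
  b2 <- monthly_dispersion_bearings(s2, dep)
  expect_equal(b2$bearing_deg, 90, tolerance = 1e-9)

  # south-west displacement from 78 N matches the closed-form oracle
  s3 <- make_series(rep(1.1, 5), lon = 10 - (0:4) * 0.25,
                    lat = 78 - (0:4) * 0.25,
                    t0 = as.POSIXct("2019-09-25", tz = "UTC"))
  b3 <- monthly_dispersion_bearings(s3, dep)
  expect_gt(b3$bearing_deg, 180); expect_lt(b3$bearing_deg, 270)
  expect_equal(b3$bearing_deg, bearing_oracle(10, 78, 9, 77),
               tolerance = 1e-6)

  # non-departed individuals yield no bearings
  nd <- dplyr::mutate(dep, departed = FALSE)
  expect_equal(nrow(monthly_dispersion_bearings(s, nd)), 0)
})

test_that("Rayleigh statistic hits its closed-form endpoints", {
  expect_equal(rayleigh_test(rep(123.4, 8))$r_bar, 1, tolerance = 1e-12)
  expect_equal(rayleigh_test(c(0, 180))$r_bar, 0, tolerance = 1e-12)
  expect_lt(rayleigh_test(rep(200, 20))$p_value, 0.001)
  expect_error(rayleigh_test(90), "at least 2")
})

test_that("detected departures track ground truth on a synthetic fleet", {
  # offshore start region so the 150-km rule is met at departure
  env <- make_flat_env(lon = seq(-20, 20, 2), lat = seq(50, 80, 2))
  # pre-departure switching is fast (no 48-h transit runs by chance);
  # the committed post-departure transit leg is what the rule should find
  cfg <- sim_config(
    n_individuals = 4, steps_per_track = 300, resident_frac = 0,
    residency_days_range = c(4, 10),
    switch_probs = matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2, byrow = TRUE),
    start_region = cbind(lon = c(-1, 1, 1, -1),
                         lat = c(74, 74, 75, 75)),
    seed = 91)
  fleet <- generate_fleet(cfg, env)
  truth_states <- fleet$truth |>
    dplyr::mutate(segment = paste0(id, "_seg1"),
                  b_mean = ifelse(state == 1, 1, 2),
                  b_class = ifelse(state == 1, "transit", "ARS"),
                  coast_dist = 1000)
  det <- truth_states |>
    dplyr::group_split(id) |>
    purrr::map_dfr(detect_departure)
  cmp <- dplyr::inner_join(det, fleet$departures, by = "id")
  expect_true(all(cmp$departed))
  lag_steps <- abs(as.numeric(cmp$departure_time) -
                     as.numeric(cmp$departure_time_true)) / 7200
  expect_true(all(lag_steps <= 3))
})
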