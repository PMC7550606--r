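toy_csv <- function(rows) {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,timestamp,lon,lat,lc", rows), f)
  f
}

test_that("Z-class rows are removed and rows come back sorted", {
  f <- toy_csv(c(
    "w1,2019-09-21T10:00:00Z,10.0,78.0,B",
    "w1,2019-09-21T08:00:00Z,10.1,78.1,A",
    "w1,2019-09-21T12:00:00Z,10.2,78.2,Z",
    "w1,2019-09-21T14:00:00Z,10.3,78.3,1",
    "w2,2019-09-21T09:00:00Z,11.0,77.0,0"))
  x <- read_argos_csv(f)
  expect_equal(nrow(x), 4)
  expect_false(any(x$lc == "Z"))
  expect_equal(attr(x, "n_z_removed"), 1L)
  expect_true(!is.unsorted(x$timestamp[x$id == "w1"]))
  expect_equal(x$lc[x$id == "w1"], c("A", "B", "1"))
})

test_that("missing columns and malformed rows are reported", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,timestamp,lon", "w1,2019-09-21T10:00:00Z,10"), f)
  expect_error(read_argos_csv(f), "lat")
  f2 <- toy_csv(c("w1,not-a-time,10,78,B",
                  "w1,2019-09-21T10:00:00Z,10,78,B",
                  "w1,2019-09-21T11:00:00Z,10,95,B")) # bad latitude
  expect_warning(x <- read_argos_csv(f2), "malformed")
  expect_equal(nrow(x), 1)
})

test_that("duplicate timestamps keep the better location class", {
  f <- toy_csv(c("w1,2019-09-21T10:00:00Z,10.0,78.0,B",
                 "w1,2019-09-21T10:00:00Z,10.1,78.1,1",
                 "w1,2019-09-21T12:00:00Z,10.2,78.2,A"))
  x <- read_argos_csv(f)
  expect_equal(nrow(x), 2)
  expect_equal(x$lc[1], "1")
})

test_that("simulated fleet CSV round-trips through write/read", {
  cfg <- sim_config(steps_per_track = 60, seed = 17)
  tr <- simulate_switching_dcrw(cfg)
  obs <- observe_with_argos_errors(tr, cfg, id = "w9")
  f <- tempfile(fileext = ".csv")
  write_argos_csv(obs, f)
  back <- read_argos_csv(f, drop_z = TRUE)
  ref <- tidy_argos(obs, drop_z = TRUE)
  expect_equal(nrow(back), nrow(ref))
  expect_equal(back$lon, ref$lon, tolerance = 1e-12)
  expect_equal(as.numeric(back$timestamp),
               trunc(as.numeric(ref$timestamp))) # ISO-8601 second precision
  expect_equal(back$lc, ref$lc)
})

make_track <- function(times_d, id = "w1") {
  tibble::tibble(
    id = id,
    timestamp = as.POSIXct("2019-09-21 00:00:00", tz = "UTC") +
      times_d * 86400,
    lon = 10 + seq_along(times_d) * 0.01, lat = 78, lc = "B")
}

test_that("tracks split at gaps over the threshold and short bits drop", {
  # locations daily over days 0-10 with silence spanning days 4-9
  x <- make_track(c(0:4, 9:10))
  s <- filter_and_split(x, gap_days = 4, min_days = 3)
  expect_equal(dplyr::n_distinct(s$segment), 1) # days 9-10 span < 3 d
  expect_equal(attr(s, "n_short_dropped"), 2L)
  s2 <- filter_and_split(make_track(c(0:4, 9:13)), gap_days = 4,
                         min_days = 3)
  expect_equal(dplyr::n_distinct(s2$segment), 2)
  # a gap of exactly 4 days does not split
  s3 <- filter_and_split(make_track(c(0:3, 7:10)), gap_days = 4,
                         min_days = 3)
  expect_equal(dplyr::n_distinct(s3$segment), 1)
  # a segment spanning exactly 3 days is kept
  s4 <- filter_and_split(make_track(c(0, 1, 2, 3)), min_days = 3)
  expect_equal(nrow(s4), 4)
})

test_that("a continuous track stays one untouched segment", {
  x <- make_track(seq(0, 30, by = 0.25))
  s <- filter_and_split(x)
  expect_equal(dplyr::n_distinct(s$segment), 1)
  expect_equal(s$timestamp, x$timestamp)
  expect_equal(attr(s, "n_short_dropped"), 0L)
})

test_that("splitting is idempotent and conserves location counts", {
  set.seed(4)
  days <- sort(c(runif(40, 0, 6), runif(40, 12, 20), runif(10, 26, 27)))
  x <- make_track(days)
  s1 <- filter_and_split(x)
  s2 <- filter_and_split(dplyr::select(s1, -segment))
  expect_equal(s2$timestamp, s1$timestamp)
  expect_equal(dplyr::n_distinct(s2$segment),
               dplyr::n_distinct(s1$segment))
  expect_equal(nrow(s1) + attr(s1, "n_short_dropped"), nrow(x))
})

test_that("empty input yields an empty segmentation, not an error", {
  s <- filter_and_split(make_track(numeric(0)))
  expect_equal(nrow(s), 0)
})

test_that("track summaries give haversine distances and class counts", {
  x <- tibble::tibble(
    id = "w1",
    timestamp = as.POSIXct("2019-09-21 00:00:00", tz = "UTC") +
      c(0, 3600),
    lon = c(10, 10), lat = c(70, 71), lc = c("B", "A"))
  s <- track_summary(x)
  expect_equal(s$dist_mean_km, 111.19, tolerance = 0.01)
  expect_equal(s$dur_mean_h, 1)
  expect_equal(s$n_A + s$n_B, 2L)
  # identical points: zero distance, duration = the time difference
  y <- dplyr::mutate(x, lat = 70)
  expect_equal(track_summary(y)$dist_mean_km, 0)
  # single location: absent distance/duration fields
  s1 <- track_summary(x[1, ])
  expect_true(is.na(s1$dist_mean_km) && is.na(s1$dur_mean_h))
})

test_that("summary mean interval matches the configured simulator rate", {
  cfg <- sim_config(steps_per_track = 2000, gap_prob = 0,
                    mean_interval_h = 1.4, seed = 23)
  tr <- simulate_switching_dcrw(cfg)
  obs <- tidy_argos(observe_with_argos_errors(tr, cfg, id = "w1"))
  s <- track_summary(obs)
  se <- 1.4 / sqrt(s$n)
  expect_lt(abs(s$dur_mean_h - 1.4), 3 * se)
})
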