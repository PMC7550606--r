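test_that("zero-noise DCRW decays the displacement geometrically", {
  cfg <- sim_config(steps_per_track = 12, gamma = c(0.9, 0),
                    sigma_proc = c(1e-15, 1e-15),
                    switch_probs = diag(2), seed = 2)
  tr <- simulate_switching_dcrw(cfg, start = c(0, 0), init_state = 1,
                                init_disp = c(0.1, 0))
  # displacement entering row t+1 has been damped t times
  expect_equal(diff(tr$lon), 0.9^(1:11) * 0.1, tolerance = 1e-9)
  expect_true(all(diff(tr$lon) > 0))      # monotone eastward
  expect_equal(tr$lat, rep(0, 12), tolerance = 1e-10)
})

test_that("identity switching matrix keeps the chain in its start state", {
  cfg <- sim_config(steps_per_track = 100, switch_probs = diag(2),
                    seed = 5)
  tr <- simulate_switching_dcrw(cfg, init_state = 2L)
  expect_true(all(tr$state == 2L))
})

test_that("state occupancy converges to the chain's stationary law", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  # oracle: left eigenvector of P with eigenvalue 1
  ev <- eigen(t(P))
  pi_stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_stat <- pi_stat / sum(pi_stat)
  expect_equal(pi_stat[1], 2 / 3, tolerance = 1e-12)
  cfg <- sim_config(steps_per_track = 1e5, switch_probs = P, seed = 9)
  tr <- simulate_switching_dcrw(cfg)
  se <- sqrt(pi_stat[1] * (1 - pi_stat[1]) / 1e5)
  # Markov dependence inflates the naive SE; allow a wide multiple
  expect_lt(abs(mean(tr$state == 1) - 2 / 3), 12 * se)
})

test_that("simulation is bitwise reproducible under a fixed seed", {
  cfg <- sim_config(steps_per_track = 80, seed = 33)
  a <- simulate_switching_dcrw(cfg)
  b <- simulate_switching_dcrw(cfg)
  expect_identical(a, b)
  oa <- observe_with_argos_errors(a, cfg)
  ob <- observe_with_argos_errors(b, cfg)
  expect_identical(oa, ob)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(switch_probs = matrix(c(0.9, 0.2, 0.2, 0.8),
                                                2, 2)),
               "row-stochastic")
  expect_error(sim_config(class_mix = c(`3` = 0.5, `2` = 0.6, `1` = 0,
                                        `0` = 0, A = 0, B = 0, Z = 0)),
               "probability vector")
  cfg <- sim_config()
  cfg$steps_per_track <- 1
  expect_error(simulate_switching_dcrw(cfg), "at least 2")
})

test_that("zero-error observations lie on the piecewise-linear path", {
  cfg <- sim_config(steps_per_track = 50, gap_prob = 0, seed = 12)
  cfg$error_scales$scale[] <- 1e-12
  tr <- simulate_switching_dcrw(cfg)
  obs <- observe_with_argos_errors(tr, cfg)
  lon_interp <- approx(as.numeric(tr$time), tr$lon,
                       xout = as.numeric(obs$timestamp))$y
  lat_interp <- approx(as.numeric(tr$time), tr$lat,
                       xout = as.numeric(obs$timestamp))$y
  expect_equal(obs$lon, lon_interp, tolerance = 1e-7)
  expect_equal(obs$lat, lat_interp, tolerance = 1e-7)
})

test_that("t-error SD converges to the class scale as df grows large", {
  cfg <- sim_config(steps_per_track = 4000, gap_prob = 0,
                    mean_interval_h = 0.8, seed = 14)
  cfg$error_scales$scale[] <- 0.05
  cfg$error_scales$df[] <- 1e6
  tr <- simulate_switching_dcrw(cfg)
  obs <- observe_with_argos_errors(tr, cfg)
  err <- obs$lat - approx(as.numeric(tr$time), tr$lat,
                          xout = as.numeric(obs$timestamp))$y
  expect_equal(sd(err), 0.05, tolerance = 0.03)
})

test_that("fleet members start inside the polygon and truth is consistent", {
  env <- generate_env_grids(lon_range = c(0, 20), lat_range = c(70, 80),
                            resolution = 0.5, seed = 3)
  cfg <- sim_config(n_individuals = 6, steps_per_track = 60,
                    resident_frac = 0.5, seed = 8)
  fleet <- generate_fleet(cfg, env)
  first <- fleet$truth |>
    dplyr::group_by(id) |>
    dplyr::slice_head(n = 1)
  expect_true(all(point_in_poly_test(first$lon, first$lat,
                                     cfg$start_region)))
  expect_equal(sum(is.na(fleet$departures$departure_time_true)), 3)
  # residents carry no departure, migrants exactly one each
  expect_true(all(fleet$departures$resident ==
                    is.na(fleet$departures$departure_time_true)))
  # no true position on land
  on_land <- mapply(function(lon, lat) {
    i <- which.min(abs(env$lon - lon)); j <- which.min(abs(env$lat - lat))
    env$land_mask[i, j]
  }, fleet$truth$lon, fleet$truth$lat)
  expect_false(any(on_land))
})

test_that("resident-only fleets never depart", {
  env <- generate_env_grids(lon_range = c(0, 20), lat_range = c(70, 80),
                            resolution = 1, seed = 3)
  cfg <- sim_config(n_individuals = 3, steps_per_track = 40,
                    resident_frac = 1, seed = 4)
  fleet <- generate_fleet(cfg, env)
  expect_true(all(is.na(fleet$departures$departure_time_true)))
})

test_that("migrant ground-truth departure equals the end of residency", {
  env <- generate_env_grids(lon_range = c(-10, 20),
                            lat_range = c(60, 80),
                            resolution = 1, seed = 3)
  cfg <- sim_config(n_individuals = 2, steps_per_track = 200,
                    resident_frac = 0, residency_days_range = c(5, 5),
                    seed = 19)
  fleet <- generate_fleet(cfg, env)
  dep <- fleet$departures
  starts <- fleet$truth |>
    dplyr::group_by(id) |>
    dplyr::summarise(t0 = min(time))
  lag_d <- as.numeric(dep$departure_time_true - starts$t0,
                      units = "days")
  expect_equal(lag_d, rep(5, 2), tolerance = 2 / 24) # 5 d to grid rounding
})
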