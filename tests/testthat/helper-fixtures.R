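# Shared fixture builders and independent oracles, all generated in code.

# a classified state series on a regular grid
make_series <- function(b_mean, coast_dist = NULL, id = "w1",
                        t0 = as.POSIXct("2019-09-21 12:00:00", tz = "UTC"),
                        step_h = 2, lon = NULL, lat = NULL) {
  n <- length(b_mean)
  tibble::tibble(
    id = id, segment = paste0(id, "_seg1"),
    time = t0 + (seq_len(n) - 1) * step_h * 3600,
    lon = if (is.null(lon)) rep(10, n) else lon,
    lat = if (is.null(lat)) rep(75, n) else lat,
    b_mean = b_mean,
    b_class = classify_behaviour(b_mean),
    coast_dist = if (is.null(coast_dist)) rep(200, n) else coast_dist)
}

# a minimal env_grids object built by hand (synthetic; no generator RNG)
make_flat_env <- function(lon = seq(0, 20, by = 1),
                          lat = seq(70, 80, by = 1),
                          depth_val = 1000, sst_val = 5,
                          land_cells = NULL) {
  nx <- length(lon); ny <- length(lat)
  land <- matrix(FALSE, nx, ny)
  if (!is.null(land_cells)) land[land_cells] <- TRUE
  depth <- matrix(depth_val, nx, ny); depth[land] <- NA
  sst <- array(sst_val, c(nx, ny, 12))
  for (m in 1:12) sst[, , m][land] <- NA
  coast <- matrix(1000, nx, ny); coast[land] <- 0
  structure(list(lon = lon, lat = lat, depth = depth, sst = sst,
                 coast_dist = coast, land_mask = land),
            class = "env_grids")
}

# independent product-limit estimator (hand-rolled oracle)
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# exhaustive Ward.D2 agglomeration via Lance-Williams updates (oracle)
ward_oracle <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > k) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      i <- active[a]; j <- active[b]
      if (d[i, j] < bd) { bd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bd)
    for (m in active) {
      if (m == i || m == j) next
      d_new <- sqrt(((sizes[i] + sizes[m]) * d[i, m]^2 +
                     (sizes[j] + sizes[m]) * d[j, m]^2 -
                     sizes[m] * d[i, j]^2) /
                    (sizes[i] + sizes[j] + sizes[m]))
      d[i, m] <- d[m, i] <- d_new
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  lab <- integer(n)
  for (g in seq_along(active)) lab[members[[active[g]]]] <- g
  lab
}

# canonical partition representation for label-free comparison
partition_signature <- function(labels) {
  match(labels, unique(labels))
}

point_in_poly_test <- function(lon, lat, poly) {
  arstrack:::point_in_polygon(lon, lat, poly)
}

# initial great-circle bearing, closed form (oracle)
bearing_oracle <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dl <- (lon2 - lon1) * r
  y <- sin(dl) * cos(lat2 * r)
  x <- cos(lat1 * r) * sin(lat2 * r) -
    sin(lat1 * r) * cos(lat2 * r) * cos(dl)
  (atan2(y, x) / r + 360) %% 360
}

# daily-ARS records with a planted covariate-response law
make_daily <- function(n_id, days_per_id, p_fun, covariate_values,
                       seed, n_locs = 12) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_id), function(i) {
    x <- covariate_values[sample.int(length(covariate_values),
                                     days_per_id, replace = TRUE)]
    p <- p_fun(x)
    tibble::tibble(
      id = paste0("w", i),
      date = as.Date("2019-09-21") + seq_len(days_per_id),
      prop_ars = rbinom(days_per_id, n_locs, p) / n_locs,
      n_locs = n_locs,
      day_index = seq_len(days_per_id),
      mean_depth = x, mean_sst = x / 300)
  })
}

# ARS-patch descriptor tables
make_feature_table <- function(m) {
  colnames(m) <- c("start_day", "mean_depth_m", "mean_sst_c",
                   "duration_days", "mcp_area_km2")
  dplyr::bind_cols(
    tibble::tibble(id = paste0("w", seq_len(nrow(m))),
                   start_time = as.POSIXct("2019-09-21", tz = "UTC")),
    tibble::as_tibble(m))
}

toy_table <- function(seed = 1, n = 6) {
  set.seed(seed)
  make_feature_table(cbind(runif(n, 0, 60), runif(n, 100, 3000),
                           runif(n, -1, 18), runif(n, 0.5, 20),
                           runif(n, 10, 5000)))
}

# small simulated fleet + fit, shared by the sssm tests
small_fit_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(steps_per_track = 150, seed = 21)
    obs <- lapply(1:2, function(i) {
      tr <- simulate_switching_dcrw(cfg, seed = 21 + i)
      observe_with_argos_errors(tr, cfg, id = paste0("w", i),
                                seed = 50 + i)
    })
    segs <- filter_and_split(tidy_argos(dplyr::bind_rows(obs)))
    fit <- fit_hsssm(segs, mcmc_config(n_chains = 2, n_iter = 3000,
                                       n_burn = 1500, thin = 5,
                                       seed = 3))
    cache <<- list(cfg = cfg, segs = segs, fit = fit)
    cache
  }
})
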