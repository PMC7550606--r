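# Ground-truthed simulation of switching DCRW tracks with Argos-style
# observation error. The process model operates directly on lon/lat degrees,
# matching the convention of the switching state-space fitter.

#' Default Argos location-class error model
#'
#' Per-class scale (degrees) and degrees of freedom of the t-distributed
#' observation error, for classes 3, 2, 1, 0, A, B and Z. The defaults sit
#' at the small end of published Argos error magnitudes because modern
#' CLS-processed (Kalman-filtered) locations are considerably more precise
#' than raw least-squares fixes; they are configuration values, used
#' symmetrically by the simulator and the state-space fitter.
#'
#' @return A tibble with columns `lc`, `scale` (degrees) and `df`.
#' @export
argos_error_defaults <- function() {
  tibble::tibble(
    lc    = c("3", "2", "1", "0", "A", "B", "Z"),
    scale = c(0.0015, 0.003, 0.006, 0.012, 0.02, 0.03, 0.08),
    df    = c(10, 10, 6, 5, 4, 4, 2)
  )
}

#' Simulation configuration for a synthetic Argos fleet
#'
#' Bundles every knob of the synthetic-data generator: the two-state
#' switching first-difference correlated random walk (DCRW) that produces
#' true paths on a regular 2-h grid, the Argos observation process that
#' degrades them, and the fleet-level residency/migration regime.
#'
#' State 1 is transiting (persistent, directed), state 2 is area-restricted
#' search (ARS; tortuous, slow). Defaults emulate autumn fin-whale tracks
#' from a high-Arctic tagging site: ~25 individuals tagged in late
#' September near 78 N 10 E, a 1.4-h mean inter-location interval, the
#' 1/2/3/4/20/70 percent class mix for classes 3/2/1/0/A/B (plus 2 percent
#' unusable Z fixes), and a residency-then-southwest-migration regime.
#'
#' @param n_individuals Number of tracks to simulate.
#' @param start_date POSIXct UTC deployment instant of the fleet.
#' @param start_region Two-column matrix (lon, lat) of polygon vertices
#'   within which all individuals start; the default is a ~375 km^2
#'   tagging polygon near 78 N 10 E.
#' @param steps_per_track Number of 2-h grid steps per track (single value
#'   or per-individual vector).
#' @param time_step_h Grid spacing in hours.
#' @param gamma Length-2 movement persistence, `c(transit, ars)`, each in
#'   \[0, 1\].
#' @param theta Length-2 mean turning angle in radians, `c(transit, ars)`;
#'   0 maintains heading, pi reverses it.
#' @param sigma_proc Process-noise SD in degrees, `c(lon, lat)`.
#' @param switch_probs 2x2 row-stochastic behavioural transition matrix
#'   `P(b[t+1] | b[t])`.
#' @param class_mix Probability vector over classes 3, 2, 1, 0, A, B, Z.
#' @param error_scales Tibble as [argos_error_defaults()].
#' @param mean_interval_h Mean of the exponential inter-observation
#'   interval, hours.
#' @param gap_prob Probability that a track contains one multi-day
#'   transmission gap.
#' @param gap_days_range Length-2 range (days) of gap durations.
#' @param resident_frac Fraction of individuals that never depart.
#' @param residency_days_range Range (days) of pre-departure residency for
#'   migrants.
#' @param migration_drift Deterministic innovation (degrees lon, lat) added
#'   to the displacement at each post-departure transiting step; the
#'   persistence term compounds it by roughly `1 / (1 - gamma_transit)`,
#'   so the default sustains a south-westerly leg of a few km/h.
#' @param commit_steps Number of forced-transit steps immediately after a
#'   migrant's departure (a committed directed leave).
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 25,
                       start_date = as.POSIXct("2019-09-21 08:00:00",
                                               tz = "UTC"),
                       start_region = cbind(
                         lon = c(9.6, 10.4, 10.4, 9.6),
                         lat = c(78.0, 78.0, 78.18, 78.18)),
                       steps_per_track = 360,
                       time_step_h = 2,
                       gamma = c(transit = 0.82, ars = 0.009),
                       theta = c(transit = 0, ars = pi),
                       sigma_proc = c(lon = 0.03, lat = 0.015),
                       switch_probs = matrix(c(0.95, 0.05, 0.05, 0.95),
                                             2, 2, byrow = TRUE),
                       class_mix = c(`3` = 0.01, `2` = 0.02, `1` = 0.03,
                                     `0` = 0.04, A = 0.20, B = 0.68,
                                     Z = 0.02),
                       error_scales = argos_error_defaults(),
                       mean_interval_h = 1.4,
                       gap_prob = 0.1,
                       gap_days_range = c(1.5, 5),
                       resident_frac = 0.4,
                       residency_days_range = c(2, 25),
                       migration_drift = c(lon = -0.016, lat = -0.006),
                       commit_steps = 30,
                       seed = 1L) {
  cfg <- list(
    n_individuals = n_individuals, start_date = start_date,
    start_region = start_region, steps_per_track = steps_per_track,
    time_step_h = time_step_h, gamma = gamma, theta = theta,
    sigma_proc = sigma_proc, switch_probs = switch_probs,
    class_mix = class_mix, error_scales = error_scales,
    mean_interval_h = mean_interval_h, gap_prob = gap_prob,
    gap_days_range = gap_days_range, resident_frac = resident_frac,
    residency_days_range = residency_days_range,
    migration_drift = migration_drift, commit_steps = commit_steps,
    seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    "gamma must lie in [0, 1]" = all(cfg$gamma >= 0 & cfg$gamma <= 1),
    "sigma_proc must be positive" = all(cfg$sigma_proc >= 0),
    "error scales must be positive" = all(cfg$error_scales$scale > 0),
    "mean_interval_h must be positive" = cfg$mean_interval_h > 0
  )
  if (any(cfg$switch_probs < 0) ||
      any(abs(rowSums(cfg$switch_probs) - 1) > 1e-8))
    stop("switch_probs must be a row-stochastic 2x2 matrix")
  if (abs(sum(cfg$class_mix) - 1) > 1e-8 || any(cfg$class_mix < 0))
    stop("class_mix must be a probability vector over 3,2,1,0,A,B,Z")
  invisible(cfg)
}

rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Simulate one switching DCRW track
#'
#' Generates a true path on the regular time grid under the two-state
#' first-difference correlated random walk
#' `d[t] = gamma[b] T(theta[b]) d[t-1] + eta[t]`, `x[t] = x[t-1] + d[t]`,
#' where `b` follows a Markov chain with transition matrix
#' `config$switch_probs` and `eta` is bivariate normal with SDs
#' `config$sigma_proc`. Displacements are in raw lon/lat degrees.
#'
#' @param config A [sim_config()].
#' @param start Length-2 start position `c(lon, lat)`.
#' @param init_state Initial behavioural state (1 transit, 2 ARS).
#' @param init_disp Displacement (degrees) feeding the first step.
#' @param forced_states Optional integer vector overriding the Markov chain
#'   for its first `length(forced_states)` steps.
#' @param drift Optional per-step displacement (degrees) added while in the
#'   transit state (used for migration legs).
#' @param drift_from Step index from which `drift` applies (1 = whole
#'   track).
#' @param env Optional [generate_env_grids()] object; steps that would land
#'   on land are redrawn.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A tibble with columns `time`, `lon`, `lat`, `state` — the ground
#'   truth (`state` 1 = transit, 2 = ARS).
#' @export
simulate_switching_dcrw <- function(config, start = c(10, 78.1),
                                    init_state = 1L,
                                    init_disp = c(0.05, 0),
                                    forced_states = NULL,
                                    drift = c(0, 0),
                                    drift_from = 1L,
                                    env = NULL,
                                    seed = config$seed) {
  validate_sim_config(config)
  n <- config$steps_per_track[1]
  if (n < 2) stop("steps_per_track must be at least 2")
  if (!is.null(seed)) set.seed(seed)

  P <- config$switch_probs
  rot <- list(rotation2(config$theta[1]), rotation2(config$theta[2]))
  sig <- config$sigma_proc

  b <- integer(n)
  b[1] <- init_state
  for (t in 2:n) b[t] <- sample.int(2L, 1L, prob = P[b[t - 1], ])
  if (!is.null(forced_states)) {
    k <- min(length(forced_states), n)
    b[seq_len(k)] <- forced_states[seq_len(k)]
    # resume the chain consistently after the forced stretch
    if (k < n) for (t in (k + 1):n) b[t] <- sample.int(2L, 1L, prob = P[b[t - 1], ])
  }

  x <- matrix(NA_real_, n, 2)
  x[1, ] <- start
  d <- init_disp
  for (t in 2:n) {
    for (try in 1:50) {
      eta <- rnorm(2, 0, sig)
      d_new <- drop(config$gamma[b[t]] * rot[[b[t]]] %*% d) + eta
      if (b[t] == 1L && t >= drift_from) d_new <- d_new + drift
      cand <- x[t - 1, ] + d_new
      if (is.null(env) || !env_is_land(env, cand[1], cand[2])) break
      d_new <- c(0, 0) # give up: stay put rather than beach
      cand <- x[t - 1, ]
    }
    d <- d_new
    x[t, ] <- cand
  }

  tibble::tibble(
    time = config$start_date + (seq_len(n) - 1) * config$time_step_h * 3600,
    lon = x[, 1], lat = x[, 2], state = b)
}

#' Degrade a true path into irregular Argos observations
#'
#' Observation times are drawn as exponential inter-arrivals with mean
#' `config$mean_interval_h` (plus an optional multi-day gap); each
#' observation linearly interpolates the true path between bracketing grid
#' times, receives a location class drawn from `config$class_mix`, and is
#' perturbed with t-distributed error at that class's scale and df. Z-class
#' rows carry the largest error scale; they exist to exercise the quality
#' filter.
#'
#' @param truth Tibble from [simulate_switching_dcrw()].
#' @param config A [sim_config()].
#' @param id Animal identifier attached to the output.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A tibble of raw locations: `id`, `timestamp`, `lon`, `lat`, `lc`.
#' @export
observe_with_argos_errors <- function(truth, config, id = "sim1",
                                      seed = config$seed) {
  if (nrow(truth) == 0) stop("truth path is empty")
  if (!is.null(seed)) set.seed(seed)
  t0 <- as.numeric(truth$time[1])
  t1 <- as.numeric(truth$time[nrow(truth)])
  span_h <- (t1 - t0) / 3600

  # exponential arrivals over the track span
  n_exp <- ceiling(span_h / config$mean_interval_h * 1.5) + 20
  gaps_h <- rexp(n_exp, rate = 1 / config$mean_interval_h)
  tt <- t0 + cumsum(gaps_h) * 3600
  tt <- tt[tt <= t1]
  if (length(tt) == 0) stop("track span too short for any observation")

  # one multi-day transmission gap, sometimes
  if (runif(1) < config$gap_prob && span_h > 24 * config$gap_days_range[2] * 2) {
    glen <- runif(1, config$gap_days_range[1], config$gap_days_range[2]) * 86400
    gstart <- runif(1, t0 + 0.2 * (t1 - t0), t1 - glen)
    tt <- tt[tt < gstart | tt > gstart + glen]
  }

  n <- length(tt)
  lon_true <- stats::approx(as.numeric(truth$time), truth$lon, xout = tt)$y
  lat_true <- stats::approx(as.numeric(truth$time), truth$lat, xout = tt)$y

  lc <- sample(names(config$class_mix), n, replace = TRUE,
               prob = config$class_mix)
  es <- config$error_scales
  scale <- es$scale[match(lc, es$lc)]
  df <- es$df[match(lc, es$lc)]

  tibble::tibble(
    id = id,
    timestamp = as.POSIXct(tt, tz = "UTC", origin = "1970-01-01"),
    lon = lon_true + scale * rt(n, df),
    lat = lat_true + scale * rt(n, df),
    lc = lc)
}

# even-odd point-in-polygon test; poly is a 2-column (lon, lat) matrix
point_in_polygon <- function(lon, lat, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(lon))
  for (k in seq_len(n)) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[j[k], 1]; yj <- poly[j[k], 2]
    cross <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
  }
  inside
}

#' Simulate a whole tagged fleet with ground truth
#'
#' All individuals start inside `config$start_region` on the deployment
#' date. A `config$resident_frac` fraction are residents (the switching
#' DCRW keeps them near the tagging area for the whole track); the rest are
#' migrants that, after a drawn residency time, depart on a committed
#' south-west transit leg and then resume behavioural switching with a
#' persistent migration drift. The true departure time of each migrant is
#' recorded.
#'
#' @param config A [sim_config()].
#' @param env An [generate_env_grids()] object covering the start region.
#' @return A list with `obs` (raw Argos-style locations for the whole
#'   fleet), `truth` (per-individual true paths and states) and
#'   `departures` (tibble `id`, `departure_time_true`, `NA` for residents).
#' @export
generate_fleet <- function(config, env) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  steps <- rep_len(config$steps_per_track, n)

  # rejection-sample ocean start points inside the polygon
  rng <- apply(config$start_region, 2, range)
  if (rng[1, 1] < min(env$lon) || rng[2, 1] > max(env$lon) ||
      rng[1, 2] < min(env$lat) || rng[2, 2] > max(env$lat))
    stop("start_region lies outside the environmental grid domain")
  starts <- matrix(NA_real_, n, 2)
  filled <- 0
  while (filled < n) {
    lon <- runif(1, rng[1, 1], rng[2, 1])
    lat <- runif(1, rng[1, 2], rng[2, 2])
    if (point_in_polygon(lon, lat, config$start_region) &&
        !env_is_land(env, lon, lat)) {
      filled <- filled + 1
      starts[filled, ] <- c(lon, lat)
    }
  }

  is_resident <- seq_len(n) <= round(config$resident_frac * n)
  ids <- sprintf("whale_%02d", seq_len(n))
  step_s <- config$time_step_h * 3600

  truths <- vector("list", n)
  obs <- vector("list", n)
  dep <- rep(as.POSIXct(NA, tz = "UTC"), n)

  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$steps_per_track <- steps[i]
    # stagger deployments within a few hours of the fleet start
    cfg_i$start_date <- config$start_date + runif(1, 0, 3 * 3600)
    heading <- runif(1, 0, 2 * pi)
    init_disp <- 0.04 * c(cos(heading), sin(heading) / 2)

    if (is_resident[i]) {
      tr <- simulate_switching_dcrw(cfg_i, start = starts[i, ],
                                    init_state = sample.int(2L, 1L),
                                    init_disp = init_disp,
                                    env = env, seed = NULL)
    } else {
      res_days <- runif(1, config$residency_days_range[1],
                        min(config$residency_days_range[2],
                            steps[i] * config$time_step_h / 24 - 1))
      res_steps <- max(2L, round(res_days * 24 / config$time_step_h))
      res_steps <- min(res_steps, steps[i] - 2L)
      forced <- c(rep(NA_integer_, res_steps),
                  rep(1L, min(config$commit_steps, steps[i] - res_steps)))
      # pre-departure: free chain; post-departure: committed transit
      b_pre <- integer(res_steps)
      b_pre[1] <- sample.int(2L, 1L)
      for (t in seq_len(res_steps)[-1])
        b_pre[t] <- sample.int(2L, 1L, prob = config$switch_probs[b_pre[t - 1], ])
      forced[seq_len(res_steps)] <- b_pre
      tr <- simulate_switching_dcrw(
        cfg_i, start = starts[i, ], init_state = b_pre[1],
        init_disp = init_disp, forced_states = forced,
        drift = config$migration_drift, drift_from = res_steps + 1L,
        env = env, seed = NULL)
      dep[i] <- tr$time[res_steps + 1]
    }
    truths[[i]] <- dplyr::mutate(tr, id = ids[i], .before = 1)
    obs[[i]] <- observe_with_argos_errors(tr, cfg_i, id = ids[i],
                                          seed = NULL)
  }

  list(
    obs = dplyr::bind_rows(obs),
    truth = dplyr::bind_rows(truths),
    departures = tibble::tibble(id = ids, resident = is_resident,
                                departure_time_true = dep))
}
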