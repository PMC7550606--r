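# Fitting the two-state hierarchical switching state-space model and
# classifying behaviour along the regularised track.

#' MCMC configuration for the switching state-space fitter
#'
#' @param n_chains Number of parallel chains.
#' @param n_iter Iterations per chain.
#' @param n_burn Burn-in iterations discarded per chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param time_step_h Regular grid spacing in hours (2 h default; 4 h is
#'   the coarser alternative sometimes used as a robustness check).
#' @param seed Integer seed.
#' @return A list of class `mcmc_config` whose `n_retained` element is
#'   `n_chains * floor((n_iter - n_burn) / thin)` — the total number of
#'   posterior samples the fitter will retain.
#' @export
#' @examples
#' # the classic schedule: 2 x 180,000 draws, 100,000 burn-in, thin 40
#' mcmc_config(2, 180000, 100000, 40)$n_retained # 4000
mcmc_config <- function(n_chains = 2, n_iter = 20000, n_burn = 10000,
                        thin = 10, time_step_h = 2, seed = 7L) {
  stopifnot("n_burn must be < n_iter" = n_burn < n_iter,
            "thin must be >= 1" = thin >= 1,
            "time_step_h must be positive" = time_step_h > 0)
  if ((n_iter - n_burn) %% thin != 0)
    message("(n_iter - n_burn) not divisible by thin; taking the floor")
  cfg <- list(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
              thin = thin, time_step_h = time_step_h, seed = seed,
              n_retained = n_chains * ((n_iter - n_burn) %/% thin))
  class(cfg) <- "mcmc_config"
  cfg
}

#' Build the regular time grid and bracketing weights for one segment
#'
#' The grid runs from the first observation in steps of `time_step_h`;
#' the number of grid points is `floor(span / step) + 1`. Each observation
#' is assigned the index of its left bracketing grid point and the
#' fractional position `j` in `[0, 1)` such that its model mean is
#' `(1 - j) * x[left] + j * x[left + 1]` (observations at or beyond the
#' last grid point are attached to the final interval with `j` clamped
#' to 1).
#'
#' @param segment Tibble with `timestamp`, `lon`, `lat` for one segment,
#'   time-ordered.
#' @param time_step_h Grid spacing in hours.
#' @return List with `times` (POSIXct grid), `left` (1-based left index
#'   per observation) and `frac`.
#' @export
regularize_grid <- function(segment, time_step_h = 2) {
  tt <- as.numeric(segment$timestamp)
  span_h <- (tt[length(tt)] - tt[1]) / 3600
  n_grid <- floor(span_h / time_step_h) + 1
  if (n_grid < 2)
    stop("segment spans less than one time step; rejected")
  times <- segment$timestamp[1] + (seq_len(n_grid) - 1) * time_step_h * 3600
  pos <- (tt - tt[1]) / (time_step_h * 3600)
  left <- pmin(floor(pos), n_grid - 2) + 1 # 1-based
  frac <- pmin(pos - (left - 1), 1)
  list(times = times, left = as.integer(left), frac = frac)
}

#' Fit the hierarchical switching state-space model
#'
#' Fits the two-state switching DCRW jointly to all track segments:
#' movement parameters (persistence `gamma`, turning `theta`, process
#' noise, switching probabilities) are population-level and shared by
#' every segment, while latent locations and behavioural states are
#' sampled per segment. Observation-error scales are fixed per Argos
#' class, not estimated. State 1 (transit) is identified as the more
#' persistent state by a relabelling constraint `gamma_transit >
#' gamma_ars`.
#'
#' @param segments Tibble of cleaned, segmented locations with columns
#'   `id`, `segment`, `timestamp`, `lon`, `lat`, `lc` (see
#'   [filter_and_split()]).
#' @param cfg An [mcmc_config()].
#' @param priors List overriding any of `gamma_shape1`, `gamma_shape2`
#'   (Beta prior on each state's `gamma`), `sigma_scale` (half-normal SD
#'   for the process noise) and `dirichlet_alpha` (symmetric Dirichlet on
#'   transition rows).
#' @param obs_scales Per-class observation error table as
#'   [argos_error_defaults()].
#' @param cutoffs Posterior-mean state cutoffs passed to
#'   [classify_behaviour()].
#' @return An object of class `hsssm_fit`: list with `draws` (tibble of
#'   posterior parameter draws with `chain` and `draw` columns), `states`
#'   (tibble `id`, `segment`, `time`, `lon`, `lat`, `b_mean`, `b_class`),
#'   `n_samples_retained`, `rhat` (split-R-hat per parameter),
#'   `accept_x`, and the configuration used.
#' @export
fit_hsssm <- function(segments, cfg = mcmc_config(), priors = list(),
                      obs_scales = argos_error_defaults(),
                      cutoffs = c(transit = 1.25, ars = 1.75)) {
  stopifnot(nrow(segments) > 0)
  pri <- utils::modifyList(
    list(gamma_shape1 = 1, gamma_shape2 = 1, sigma_scale = 0.2,
         dirichlet_alpha = 1), priors)

  seg_ids <- unique(segments$segment)
  seg_data <- vector("list", length(seg_ids))
  seg_meta <- vector("list", length(seg_ids))
  for (i in seq_along(seg_ids)) {
    d <- dplyr::arrange(segments[segments$segment == seg_ids[i], ],
                        .data$timestamp)
    gr <- regularize_grid(d, cfg$time_step_h)
    # initial latent path: linear interpolation of observations onto grid
    x0 <- stats::approx(as.numeric(d$timestamp), d$lon,
                        xout = as.numeric(gr$times), rule = 2)$y
    y0 <- stats::approx(as.numeric(d$timestamp), d$lat,
                        xout = as.numeric(gr$times), rule = 2)$y
    step_km <- gc_dist_km(head(x0, -1), head(y0, -1),
                          tail(x0, -1), tail(y0, -1))
    b0 <- c(0L, as.integer(step_km < stats::median(step_km)))
    sc <- obs_scales$scale[match(d$lc, obs_scales$lc)]
    df <- obs_scales$df[match(d$lc, obs_scales$lc)]
    if (anyNA(sc)) stop("unknown location class in segment ", seg_ids[i])
    seg_data[[i]] <- list(
      x = x0, y = y0, obs_lon = d$lon, obs_lat = d$lat,
      idxL = gr$left - 1L, frac = gr$frac, scale = sc, df = df,
      b = b0, prop_x = mean(sc))
    seg_meta[[i]] <- tibble::tibble(id = d$id[1], segment = seg_ids[i],
                                    time = gr$times)
  }

  init <- list(gamma = c(0.7, 0.1), theta = c(0, 0),
               sigma = c(0.02, 0.02),
               switch_probs = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                                     byrow = TRUE))

  chains <- vector("list", cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    set.seed(cfg$seed + 1000L * ch)
    init_ch <- init
    init_ch$gamma <- pmin(pmax(init$gamma + runif(2, -0.05, 0.05),
                               0.01), 0.99)
    chains[[ch]] <- run_dcrw_chain(seg_data, init_ch, pri,
                                   cfg$n_iter, cfg$n_burn, cfg$thin)
  }

  draws <- purrr::map_dfr(seq_along(chains), function(ch) {
    m <- tibble::as_tibble(as.data.frame(chains[[ch]]$draws))
    dplyr::mutate(m, chain = ch, draw = dplyr::row_number(),
                  .before = 1)
  })

  # average posterior location/state summaries over chains
  states <- purrr::map_dfr(seq_along(seg_ids), function(i) {
    lon <- rowMeans(sapply(chains, function(c) c$segments[[i]]$lon))
    lat <- rowMeans(sapply(chains, function(c) c$segments[[i]]$lat))
    bm <- rowMeans(sapply(chains, function(c) c$segments[[i]]$b_mean))
    dplyr::mutate(seg_meta[[i]], lon = lon, lat = lat, b_mean = bm,
                  b_class = classify_behaviour(bm, cutoffs))
  })

  par_cols <- setdiff(names(draws), c("chain", "draw"))
  rhat <- vapply(par_cols, function(p) split_rhat(draws, p), numeric(1))

  out <- list(draws = draws, states = states,
              n_samples_retained = cfg$n_retained,
              rhat = rhat,
              accept_x = mean(vapply(chains, function(c) c$accept_x,
                                     numeric(1))),
              config = cfg, priors = pri, cutoffs = cutoffs)
  class(out) <- "hsssm_fit"
  out
}

# split-R-hat: split each chain in half, compare within/between variance
split_rhat <- function(draws, par) {
  halves <- draws |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(half = ifelse(.data$draw <= max(.data$draw) / 2, 1, 2)) |>
    dplyr::group_by(.data$chain, .data$half) |>
    dplyr::summarise(m = mean(.data[[par]]), v = stats::var(.data[[par]]),
                     n = dplyr::n(), .groups = "drop")
  if (any(halves$n < 2)) return(NA_real_)
  n <- min(halves$n)
  W <- mean(halves$v)
  B <- n * stats::var(halves$m)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Classify behaviour from the posterior-mean state
#'
#' Posterior means below the lower cutoff are transiting, above the upper
#' cutoff area-restricted search (ARS); everything between — including
#' values exactly at either cutoff — is uncertain.
#'
#' @param b_mean Posterior-mean behavioural state values in `[1, 2]`.
#' @param cutoffs Length-2 vector `c(transit, ars)`, default
#'   `c(1.25, 1.75)`.
#' @return Character vector with levels `"transit"`, `"uncertain"`,
#'   `"ARS"`.
#' @export
#' @examples
#' classify_behaviour(c(1.1, 1.25, 1.5, 1.75, 1.9))
classify_behaviour <- function(b_mean, cutoffs = c(1.25, 1.75)) {
  if (any(b_mean < 1 - 1e-9 | b_mean > 2 + 1e-9, na.rm = TRUE))
    stop("b_mean must lie in [1, 2]")
  dplyr::case_when(
    b_mean < cutoffs[1] ~ "transit",
    b_mean > cutoffs[2] ~ "ARS",
    TRUE ~ "uncertain")
}

#' Remove state-series locations that fall on land
#'
#' Grid rows whose nearest environmental cell is land are dropped; the
#' removal count is recorded in the `n_land_removed` attribute.
#'
#' @param series State-series tibble (see [fit_hsssm()]).
#' @param env An [generate_env_grids()] object covering the series.
#' @return The filtered series.
#' @export
drop_land_locations <- function(series, env) {
  idx <- env_cell_index(env, series$lon, series$lat) # errors if outside
  on_land <- env$land_mask[idx]
  out <- series[!on_land, , drop = FALSE]
  attr(out, "n_land_removed") <- sum(on_land)
  out
}

#' @export
print.hsssm_fit <- function(x, ...) {
  cat(sprintf(
    "<hsssm_fit> %d segments, %d grid locations, %d retained samples\n",
    dplyr::n_distinct(x$states$segment), nrow(x$states),
    x$n_samples_retained))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy posterior summary of a fitted switching state-space model
#'
#' @param x An `hsssm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per movement parameter: posterior
#'   `median`, `mean`, `sd`, central 95% interval and split-R-hat.
#' @export
tidy.hsssm_fit <- function(x, ...) {
  par_cols <- setdiff(names(x$draws), c("chain", "draw"))
  purrr::map_dfr(par_cols, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(term = p, median = stats::median(v), mean = mean(v),
                   sd = stats::sd(v),
                   conf.low = unname(stats::quantile(v, 0.025)),
                   conf.high = unname(stats::quantile(v, 0.975)),
                   rhat = unname(x$rhat[p]))
  })
}

#' One-row summary of a fitted switching state-space model
#'
#' @inheritParams tidy.hsssm_fit
#' @return A one-row tibble: segment/location counts, retained samples,
#'   worst split-R-hat, per-class label proportions.
#' @export
glance.hsssm_fit <- function(x, ...) {
  tb <- table(factor(x$states$b_class,
                     levels = c("transit", "uncertain", "ARS")))
  tibble::tibble(
    n_segments = dplyr::n_distinct(x$states$segment),
    n_locations = nrow(x$states),
    n_samples_retained = x$n_samples_retained,
    max_rhat = max(x$rhat, na.rm = TRUE),
    prop_transit = unname(tb["transit"]) / nrow(x$states),
    prop_uncertain = unname(tb["uncertain"]) / nrow(x$states),
    prop_ars = unname(tb["ARS"]) / nrow(x$states))
}
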