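# Environmental covariate extraction and smooth models of the daily
# proportion of time spent in ARS.

#' Attach environmental covariates to a state series
#'
#' Nearest-cell extraction of bathymetry (`depth`, m), sea-surface
#' temperature (`sst`, degC, matched to each location's calendar month)
#' and distance to the nearest coast (`coast_dist`, km).
#'
#' @param series State-series tibble with `time`, `lon`, `lat`.
#' @param env An [generate_env_grids()] object covering every location.
#' @return `series` with `depth`, `sst` and `coast_dist` columns added.
#' @export
extract_environment <- function(series, env) {
  idx <- env_cell_index(env, series$lon, series$lat)
  month <- as.integer(format(series$time, "%m"))
  sst <- env$sst[cbind(idx, month)]
  dplyr::mutate(series,
                depth = env$depth[idx],
                sst = sst,
                coast_dist = env$coast_dist[idx])
}

#' Daily proportion of locations classified as ARS
#'
#' One record per individual-day: the fraction of that day's grid
#' locations labelled ARS (uncertain locations stay in the denominator),
#' the location count, the day index since the 10 September origin, and
#' day-averaged environmental covariates where present.
#'
#' @param series Classified state-series tibble (may hold many
#'   individuals), optionally carrying `depth`/`sst`/`coast_dist`.
#' @param origin_date Day-0 origin; defaults to 10 September of the
#'   series' deployment season.
#' @return A tibble `id`, `date`, `prop_ars`, `n_locs`, `day_index`, and
#'   mean covariates (`mean_depth`, `mean_sst`, `mean_coast`) when
#'   available.
#' @export
daily_ars_proportion <- function(series, origin_date = NULL) {
  if (is.null(origin_date)) {
    t0 <- min(series$time)
    yr <- as.integer(format(t0, "%Y"))
    origin_date <- as.POSIXct(sprintf("%d-09-10 00:00:00", yr), tz = "UTC")
    if (origin_date > t0)
      origin_date <- as.POSIXct(sprintf("%d-09-10 00:00:00", yr - 1),
                                tz = "UTC")
  }
  has_env <- all(c("depth", "sst") %in% names(series))
  out <- series |>
    dplyr::mutate(date = as.Date(.data$time)) |>
    dplyr::group_by(.data$id, .data$date) |>
    dplyr::summarise(
      prop_ars = mean(.data$b_class == "ARS"),
      n_locs = dplyr::n(),
      mean_depth = if (has_env) mean(.data$depth, na.rm = TRUE) else NA_real_,
      mean_sst = if (has_env) mean(.data$sst, na.rm = TRUE) else NA_real_,
      mean_coast = if ("coast_dist" %in% names(series))
        mean(.data$coast_dist, na.rm = TRUE) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(day_index = as.numeric(
      as.POSIXct(.data$date, tz = "UTC") - origin_date, units = "days"))
  attr(out, "origin_date") <- origin_date
  out
}

#' Smooth model of daily ARS proportion against one covariate
#'
#' Penalized-spline logistic regression of the daily ARS proportion on a
#' single covariate, weighted by the day's location count, with a
#' random-effect intercept per individual when more than one individual
#' is present; the smoothing parameter is chosen by (RE)ML
#' cross-validation via [mgcv::gam()]. This is a deliberately simpler
#' smooth model than a full autocorrelated quasibinomial GAMM: it targets
#' the qualitative covariate relationship, and its logit link keeps
#' fitted proportions inside (0, 1).
#'
#' @param data Output of [daily_ars_proportion()].
#' @param covariate One of `"day_index"`, `"mean_depth"`, `"mean_sst"`.
#' @param k Spline basis dimension.
#' @param n_grid Length of the evaluation grid.
#' @return An object of class `ars_smooth`: tibble with the evaluation
#'   grid (`covariate` value, `fit`, `lower`, `upper` on the proportion
#'   scale), with the fitted [mgcv::gam] in attribute `model` and the
#'   effective degrees of freedom in attribute `edf`.
#' @export
fit_proportion_smooth <- function(data, covariate = "mean_depth",
                                  k = 6, n_grid = 100) {
  stopifnot(covariate %in% names(data))
  d <- data[stats::complete.cases(data[c(covariate, "prop_ars",
                                         "n_locs")]), ]
  if (nrow(d) < 10) stop("too few daily records to fit a smooth")
  if (stats::sd(d[[covariate]]) < 1e-12)
    stop("covariate '", covariate, "' is constant; cannot fit a smooth")
  d$x <- d[[covariate]]
  d$id <- factor(d$id)
  multi_id <- nlevels(d$id) > 1
  form <- if (multi_id) {
    prop_ars ~ s(x, k = k) + s(id, bs = "re")
  } else {
    prop_ars ~ s(x, k = k)
  }
  fit <- mgcv::gam(form, family = stats::binomial(), weights = d$n_locs,
                   data = d, method = "REML")
  grid <- tibble::tibble(
    x = seq(min(d$x), max(d$x), length.out = n_grid),
    id = d$id[which.max(table(d$id))][1])
  pr <- mgcv::predict.gam(
    fit, newdata = grid, type = "link", se.fit = TRUE,
    exclude = if (multi_id) "s(id)" else NULL, newdata.guaranteed = TRUE)
  eta <- as.numeric(pr$fit); se <- as.numeric(pr$se.fit)
  out <- tibble::tibble(
    covariate = covariate,
    value = grid$x,
    fit = stats::plogis(eta),
    lower = stats::plogis(eta - 1.96 * se),
    upper = stats::plogis(eta + 1.96 * se))
  attr(out, "model") <- fit
  attr(out, "edf") <- sum(fit$edf)
  class(out) <- c("ars_smooth", class(out))
  out
}
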