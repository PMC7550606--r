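# End-to-end orchestration: simulate -> ingest -> fit -> segment ->
# habitat -> typology, with persisted CSV artifacts and a manifest.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic fleet (ignored
#'   when `argos_csv` points at an existing location file).
#' @param mcmc An [mcmc_config()].
#' @param argos_csv Optional path to a raw Argos CSV to ingest instead of
#'   simulating.
#' @param env An [generate_env_grids()] object, or `NULL` to generate the
#'   default domain.
#' @param gap_days,min_days Track splitting thresholds (days).
#' @param cutoffs Behavioural-state cutoffs `c(transit, ars)`.
#' @param min_hours,min_coast_km Departure rule thresholds.
#' @param k Number of patch types for Ward clustering.
#' @param outdir Output directory for stage artifacts.
#' @param seed Master seed; stages derive their own streams from it.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(sim = sim_config(), mcmc = mcmc_config(),
                            argos_csv = NULL, env = NULL,
                            gap_days = 4, min_days = 3,
                            cutoffs = c(1.25, 1.75),
                            min_hours = 48, min_coast_km = 150,
                            k = 3, outdir = tempfile("arstrack_run_"),
                            seed = 1L) {
  structure(list(sim = sim, mcmc = mcmc, argos_csv = argos_csv,
                 env = env, gap_days = gap_days, min_days = min_days,
                 cutoffs = cutoffs, min_hours = min_hours,
                 min_coast_km = min_coast_km, k = k, outdir = outdir,
                 seed = seed),
            class = "run_config")
}

#' Run the whole analysis pipeline
#'
#' Executes every stage in order, persists intermediate artifacts as CSV
#' under `config$outdir`, and returns a manifest recording per-stage
#' outputs and the bookkeeping counts (locations read, Z-class and
#' duplicate removals, segments kept, land locations removed, phases and
#' patches found). Reruns with the same configuration and seed reproduce
#' all outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_manifest`: `counts` (named list),
#'   `paths` (named list of artifact files), and the in-memory stage
#'   results (`fit`, `states`, `phases`, `departures`, `residency`,
#'   `daily`, `clusters`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$outdir, f)
  counts <- list()

  env <- config$env
  if (is.null(env)) env <- generate_env_grids(seed = config$seed)

  # --- stage 1: simulate (or point at provided data) -------------------
  truth <- departures_true <- NULL
  if (is.null(config$argos_csv)) {
    sim <- config$sim
    sim$seed <- config$seed
    fleet <- generate_fleet(sim, env)
    write_argos_csv(fleet$obs, p("argos_raw.csv"))
    utils::write.csv(as.data.frame(fleet$truth), p("truth.csv"),
                     row.names = FALSE)
    truth <- fleet$truth
    departures_true <- fleet$departures
    argos_csv <- p("argos_raw.csv")
  } else {
    argos_csv <- config$argos_csv
  }

  # --- stage 2: ingest, filter, split ----------------------------------
  locs <- read_argos_csv(argos_csv, drop_z = TRUE)
  counts$n_read <- attr(locs, "n_read")
  counts$n_z_removed <- attr(locs, "n_z_removed")
  counts$n_dup_removed <- attr(locs, "n_dup_removed")
  segs <- filter_and_split(locs, config$gap_days, config$min_days)
  counts$n_short_dropped <- attr(segs, "n_short_dropped")
  counts$n_locations_kept <- nrow(segs)
  counts$n_segments <- dplyr::n_distinct(segs$segment)
  write_argos_csv(segs, p("segments.csv"))

  # --- stage 3: fit the switching state-space model --------------------
  cfg <- config$mcmc
  cfg$seed <- config$seed + 1L
  fit <- fit_hsssm(segs, cfg, cutoffs = config$cutoffs)
  counts$n_grid_locations <- nrow(fit$states)
  states <- drop_land_locations(fit$states, env)
  counts$n_land_removed <- attr(states, "n_land_removed")
  counts$n_samples_retained <- fit$n_samples_retained
  states <- extract_environment(states, env)
  utils::write.csv(
    dplyr::mutate(as.data.frame(states),
                  time = format(.data$time, "%Y-%m-%dT%H:%M:%SZ")),
    p("state_series.csv"), row.names = FALSE)

  # --- stage 4: segmentation -------------------------------------------
  by_id <- split(states, states$id)
  departures <- purrr::map_dfr(
    by_id, detect_departure,
    min_hours = config$min_hours, min_coast_km = config$min_coast_km,
    time_step_h = cfg$time_step_h)
  counts$n_departed <- sum(departures$departed)
  residency <- kaplan_meier_residency(departures)
  phases <- purrr::map_dfr(by_id, identify_phases,
                           cutoffs = config$cutoffs) |>
    phase_metrics(env)
  counts$n_ars_patches <- sum(phases$kind == "ARS")
  counts$n_migratory_phases <- sum(phases$kind == "migratory")
  utils::write.csv(
    as.data.frame(dplyr::select(phases, -"rows")),
    p("phases.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(departures), p("departures.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(residency), p("residency.csv"),
                   row.names = FALSE)
  bearings <- purrr::map_dfr(unique(states$id), function(i) {
    monthly_dispersion_bearings(by_id[[i]],
                                departures[departures$id == i, ])
  })
  utils::write.csv(as.data.frame(bearings), p("bearings.csv"),
                   row.names = FALSE)

  # --- stage 5: habitat ------------------------------------------------
  daily <- daily_ars_proportion(states)
  utils::write.csv(as.data.frame(daily), p("daily_ars.csv"),
                   row.names = FALSE)
  smooths <- list()
  for (cv in c("day_index", "mean_depth", "mean_sst")) {
    sm <- try(fit_proportion_smooth(daily, cv), silent = TRUE)
    if (!inherits(sm, "try-error")) {
      smooths[[cv]] <- sm
      utils::write.csv(as.data.frame(sm),
                       p(sprintf("smooth_%s.csv", cv)),
                       row.names = FALSE)
    }
  }

  # --- stage 6: patch typology -----------------------------------------
  clusters <- NULL
  feat <- patch_feature_table(phases)
  if (nrow(feat) >= max(3, config$k)) {
    clusters <- ward_clustering(pca_patches(feat), k = config$k)
    utils::write.csv(as.data.frame(clusters$table), p("patch_types.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(summarize_patch_types(clusters)),
                     p("patch_type_summary.csv"), row.names = FALSE)
    counts$n_patches_clustered <- length(clusters$assignments)
  }

  manifest <- list(
    counts = counts,
    seed = config$seed,
    paths = as.list(list.files(config$outdir, full.names = TRUE) |>
                      setNames(list.files(config$outdir))),
    truth = truth, departures_true = departures_true,
    fit = fit, states = states, departures = departures,
    residency = residency, phases = phases, daily = daily,
    smooths = smooths, clusters = clusters, env = env)
  jsonlite::write_json(counts, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %s\n", nm, x$counts[[nm]]))
  invisible(x)
}
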