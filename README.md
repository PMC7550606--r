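# arstrack

Behavioural segmentation of Argos satellite telemetry for marine
mammals: a complete, tested R implementation of the analysis chain that
takes raw, error-laden satellite fixes and turns them into behavioural
states, residency times, migration phases, foraging patches and patch
types.

## The problem

Argos tags on whales report positions irregularly (minutes to days
apart) with class-dependent errors from hundreds of metres to tens of
kilometres. The scientific questions — *when did an animal stop
"residing" and start migrating? where did it forage along the way? what
habitat do foraging patches share?* — require a regular, error-corrected
track with a behavioural label at every step. The standard solution in
movement ecology is a **two-state hierarchical switching state-space
model (hSSSM)** built on the first-difference correlated random walk
(DCRW):

d_t = γ_b · T(θ_b) · d_(t−1) + η_t,   x_t = x_(t−1) + d_t

where d_t is the displacement on a regular 2-h grid, γ_b ∈ [0, 1] is the
movement persistence of behavioural state b, T(θ_b) a rotation by the
state's mean turning angle, and η_t Gaussian process noise. State 1
(*transiting*) has γ near 1 and θ near 0 — fast directed travel; state 2
(*area-restricted search*, ARS, the operational proxy for foraging) has
γ near 0 and reversing turns. The state sequence follows a Markov chain;
observations attach to the grid by linear interpolation with
t-distributed, Argos-class-specific errors. Movement parameters are
pooled across all track segments (all individuals inform one
population-level estimate); a Metropolis-within-Gibbs sampler written in
C++ (exact forward-filtering backward-sampling for the states) draws the
posterior, and each grid location gets the posterior mean state in
[1, 2], classified as transiting (< 1.25), ARS (> 1.75) or uncertain.

Downstream of the model, the package implements the field's rule-based
definitions: departure from the residency region (first ≥ 48 h run of
transiting further than 150 km from the coast), Kaplan–Meier residency
curves with censoring for dead tags, ARS patches and migratory phases
(3-consecutive-location start/end rules), minimum-convex-polygon patch
areas on an equal-area projection, monthly dispersion bearings with a
Rayleigh test of directedness, penalized-spline models of the daily ARS
proportion against depth and SST, and PCA + Ward.D2 clustering of
patches into types.

Because real deployments cannot be rerun, the package ships a
first-class **synthetic-data generator**: ground-truthed switching-DCRW
fleets (an autumn high-Arctic deployment by default — ~375 km² tagging
polygon near 78°N, 1.4-h mean fix interval, 1/2/3/4/20/70% class mix,
residency-then-southwest-migration regime) and environmental grids
(archipelago land mask, exact coast distances, shelf–slope–basin
bathymetry, monthly SST within −1.8–19.3 °C). Every estimator is tested
against this ground truth or an independent oracle.

## Worked example

Simulate a 6-whale fleet (half residents, half migrants), fit the
switching model, and segment the tracks:

```r
library(arstrack)

env   <- generate_env_grids(lon_range = c(-40, 25),
                            lat_range = c(45, 88),
                            resolution = 1, seed = 2)
cfg   <- sim_config(n_individuals = 6, steps_per_track = 240,
                    resident_frac = 0.5, seed = 42)
fleet <- generate_fleet(cfg, env)

locs <- tidy_argos(fleet$obs)                     # Z-filter, dedupe, sort
segs <- filter_and_split(locs, gap_days = 4, min_days = 3)
fit  <- fit_hsssm(segs, mcmc_config(n_chains = 2, n_iter = 8000,
                                    n_burn = 4000, thin = 10, seed = 9))
tidy(fit)
#> # A tibble: 8 × 7
#>   term           median   mean      sd conf.low conf.high  rhat
#> 1 gamma_transit  0.883  0.884  0.0215   0.842      0.926  1.04
#> 2 gamma_ars      0.0441 0.0503 0.0370   0.00204    0.136  1.01
#> 3 theta_transit  0.0279 0.0278 0.0118   0.00468    0.0515 1.03
#> ...
```

The transit state comes back highly persistent (γ ≈ 0.88 — the migrant
legs include a sustained directional drift, which the DCRW reads as
extra persistence) and the ARS state nearly uncorrelated (γ ≈ 0.04),
with the two posteriors cleanly separated — the signature of two
distinct behavioural modes. `glance(fit)` reports 6 segments, 1,429
grid locations, 800 retained samples and the label mix (36% transiting,
42% ARS, 22% uncertain here).

```r
states <- drop_land_locations(fit$states, env) |>
  extract_environment(env)                 # DEP (m), SST (°C), COAST (km)

dep <- states |> dplyr::group_split(id) |>
  purrr::map_dfr(detect_departure)         # 48-h / 150-km rule
#> whale_06 departs 2019-09-30 22:32; the other five are censored

km <- kaplan_meier_residency(dep)          # survival curve, median NA here
phases <- states |> dplyr::group_split(id) |>
  purrr::map_dfr(identify_phases) |> phase_metrics(env)
dplyr::count(phases, kind)
#>   ARS 30, migratory 32
```

With one departure among six tags the residency curve never crosses
50%, so the median departure date is undefined — exactly the right
censoring behaviour for a short demo fleet. Patch typology then runs
`pca_patches()` + `ward_clustering()` on the ARS rows of `phases`, and
`run_pipeline(pipeline_config(...))` does all of the above in one call
with CSV artifacts and a count manifest.

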