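---
title: "Behavioural segmentation of Argos tracks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural segmentation of Argos tracks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`arstrack` implements a complete analysis chain for Argos satellite
telemetry of marine mammals: simulation of ground-truthed tracks,
preprocessing, Bayesian behavioural state estimation, rule-based
segmentation into residency, migration and foraging structures, habitat
association, and patch typology. This vignette documents the models, the
tunable parameters, and the design decisions, in enough detail that a
user can judge what a passing test suite does — and does not — say about
real data.

## The movement model

The process model is a two-state switching first-difference correlated
random walk (DCRW) on raw longitude/latitude degrees. Writing
$d_t = x_t - x_{t-1}$ for the displacement on a regular time grid
(default 2 h),

$$d_t = \gamma_{b_t} T(\theta_{b_t})\, d_{t-1} + \eta_t, \qquad
\eta_t \sim N_2(0, \mathrm{diag}(\sigma_{lon}^2, \sigma_{lat}^2)),$$

where $T(\theta)$ is a rotation matrix and $b_t \in \{1, 2\}$ is a
latent behavioural state following a first-order Markov chain with
row-stochastic transition matrix $A$. State 1 (*transiting*) has
persistence $\gamma$ near 1 and mean turning angle near 0 — fast,
directed movement. State 2 (*area-restricted search*, ARS) has $\gamma$
near 0 and reversing turns — slow, tortuous movement, commonly
interpreted as foraging. Working on degrees rather than projected
coordinates follows the convention of the established hierarchical
state-space tooling for Argos tracks, which keeps the fitted parameters
comparable with the literature; the cost is that one degree of longitude
shrinks with latitude, which the per-coordinate process SDs absorb.

Observations are irregular in time and carry class-dependent Argos
error. Each observation at fractional grid position $j_i \in [0,1)$ has
model mean $(1-j_i)x_{t-1} + j_i x_t$ and independent t-distributed
errors in each coordinate with a fixed per-class scale and degrees of
freedom. The scales are configuration constants, not estimated
parameters, used symmetrically by the simulator and the fitter. The
defaults (degrees: 0.0015/0.003/0.006/0.012/0.02/0.03 for classes
3/2/1/0/A/B, df 10/10/6/5/4/4) sit at the small end of published Argos
error magnitudes, reflecting modern Kalman-processed CLS locations
rather than raw least-squares fixes; class Z, which is only generated to
exercise the quality filter, gets scale 0.08 and df 2.

## The sampler

The posterior is explored by Metropolis-within-Gibbs, implemented in
C++:

* **Latent locations** — single-site Gaussian random-walk Metropolis,
  with a per-segment proposal scale adapted during burn-in towards ~30%
  acceptance.
* **Behavioural states** — exact forward-filtering backward-sampling
  over the 2-state chain, per segment.
* **Transition matrix** — conjugate Beta updates from the pooled
  transition counts (Dirichlet(1,1) rows a priori).
* **Movement parameters** — random-walk Metropolis on transformed
  scales: logit for each $\gamma$ (Beta(1,1) prior), wrapped for each
  $\theta$ (uniform prior), log for each $\sigma$ (half-normal prior,
  SD 0.2°). All priors are overridable.

The model is *hierarchical* in the fully pooled sense: one
population-level set of movement parameters is shared by all track
segments, which is the strongest reading of combining information across
individuals; per-individual random effects are deliberately out of
scope. Label switching is resolved by relabelling so that
$\gamma_{transit} > \gamma_{ARS}$ always, identifying state 1 as the
persistent state. Two chains are run from jittered initial values;
retained-sample bookkeeping is always
`n_chains * floor((n_iter - n_burn) / thin)`, and convergence is
summarised by split-$\hat R$ per parameter.

The behavioural state reported at each grid point is the arithmetic mean
of the retained state samples (values 1 or 2), pooled across chains, so
it lives in $[1, 2]$ and equals 1 plus the posterior probability of ARS.
Classification follows the standard cutoffs: mean < 1.25 transiting,
mean > 1.75 ARS, anything in between (boundaries included) *uncertain*.

## Preprocessing rules

Raw tables are sorted by animal and time; Z-class rows are removed;
exact duplicates are dropped; ties at the same timestamp keep the better
class (3 > 2 > 1 > 0 > A > B), then first-seen (the choice of tie-break
is ours; the convention in field datasets varies). Tracks are split
wherever the gap between consecutive locations exceeds 4 days
(strictly), and segments spanning under 3 days are discarded (exactly 3
days is kept). "Transmitting days" is interpreted as elapsed calendar
time between locations — the simplest reading consistent with a data
gap. The regular grid for each segment runs from its first observation
in 2-h steps, `floor(span/step) + 1` points.

## Segmentation rules

* **Departure** — the first run of consecutive grid locations, all
  labelled transiting and all further than 150 km from the coast,
  spanning at least 48 h; its first location is the departure time.
  Runs must be contiguous on the regular grid — removing land rows can
  break a run, which we consider correct behaviour since the rule is
  defined on the 2-h series. Both thresholds are configuration, and
  `plot_max_coast_distance()` shows the bimodality diagnostic that
  motivates the offshore threshold.
* **Residency** — a Kaplan–Meier product-limit estimate (via the
  `survival` package) of the probability of not yet having departed, in
  days since 10 September (the day-0 convention of the deployment
  season), censoring tags that die before departing. The reported band
  is the 50% (quartile) confidence envelope.
* **Phases** — a migratory phase begins after 3 or more successive
  locations with mean state < 1.25 and ends before the first run of 3
  or more locations ≥ 1.25; an ARS patch begins after 3 or more
  successive locations > 1.75 and ends before the first run of 3 or
  more ≤ 1.75. Terminating locations do not belong to the phase; short
  (< 3) interruptions do; a phase still open at track end is trimmed to
  its last qualifying location. The two rules run independently.
* **Patch metrics** — mean speed is along-track great-circle distance
  (sphere radius 6371 km) over elapsed time; patch size is the convex
  hull area in km² after a Lambert azimuthal equal-area projection
  about the patch centroid (areas on raw degrees are meaningless at
  sub-polar latitudes); fewer than 3 distinct positions, or a collinear
  hull, give area 0 with a degeneracy flag.
* **Dispersion** — monthly bearings are initial great-circle bearings
  from the departure location to the month's last position (rhumb lines
  are avoided deliberately at high latitude). The Rayleigh test reports
  the mean resultant length and the standard finite-sample
  approximation $p = \exp(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1+2n))$ with
  $R = n\bar R$; its null calibration is itself a test in the suite.

## Habitat association

Daily ARS proportions (ARS locations over all grid locations that day,
uncertain rows in the denominator) are modelled against one covariate
at a time by a penalized B-spline logistic regression, weighted by the
day's location count, with a random-effect intercept per individual,
smoothing chosen by REML (`mgcv`). This is a stated simplification of a
full quasibinomial GAMM with AR(1) residuals: the package targets the
qualitative covariate relationships (and the tests check exactly that —
sign and shape recovery), not the autocorrelation-adjusted inference of
the richer model. Distance to coast is excluded from smooth models
because it is strongly collinear with depth. Basis dimension defaults
to 6 knots; fitted curves and their pointwise 95% bands are returned on
the proportion scale, so they respect (0, 1) by construction.

## Patch typology

Each ARS patch contributes five descriptors: start day, mean depth,
mean SST, duration, and MCP area. Because the units are incommensurable
(days, m, °C, km²) the descriptors are z-scored, making the PCA a
correlation-matrix decomposition — the source conventions here are
ambiguous, and this is the only choice under which the analysis is
invariant to units. All five components are retained (no truncation),
and patches are clustered by Ward.D2 agglomeration on the scores,
heights on the Euclidean distance scale. The number of types defaults
to k = 3; because the original choice criterion is not documented, the
largest-relative-height-gap suggestion is reported alongside. Type
labels are renumbered by ascending mean start day, so "type 1" is the
early-season type.

## The synthetic-data generator

The generator is first-class, tested code: it produces the ground truth
every downstream stage is validated against. Its defaults emulate an
autumn high-Arctic fin-whale deployment: ~25 individuals released
within a ~375 km² polygon near 78°N 10°E in late September; 2-h true
paths from the switching DCRW with $\gamma = (0.82, 0.009)$,
$\theta = (0, \pi)$, process SDs (0.03, 0.015)°, symmetric 0.05
switching; observation times as exponential arrivals with mean 1.4 h
plus occasional multi-day gaps; the 1/2/3/4/20/70% class mix (classes
3/2/1/0/A/B) with 2% Z rows added so the filter stage has work to do.
A configurable fraction of individuals are residents; migrants draw a
residency time (2–25 days), then leave on a committed transit leg
(30 steps) with a persistent south-westerly drift. The committed leg
makes the true departure time sharply defined, which is what lets the
departure detector be scored against ground truth.

Environmental grids carry the same semantics as the global relief /
reconstructed-SST / coastline products a field analysis would use:
a small archipelago placed near the tagging origin (and an isolated
island down-track when the domain reaches it), exact great-circle
distance to the nearest land cell, shelf–slope–basin bathymetry between
2 and 5500 m driven by coast distance, and monthly SST declining with
latitude within −1.8 to 19.3 °C. They are synthetic stand-ins: they
reproduce envelopes and gradients, not geography.

What passing tests on this generator do **not** show: robustness to the
pathologies of real Argos data — tag-induced location clusters, duty
cycling, heteroscedastic error bursts, strong coastline interactions —
nor correctness of the fully-pooled hierarchy when individuals truly
differ in movement parameters.

## Numerical choices and problem sizes

Parameter-recovery checks run on a fleet of 8 tracks × 400 two-hour
steps (≈33 days each, matching the average real deployment length) with
MCMC schedules of 2 chains × 20,000 iterations (burn-in 10,000, thin
10); the package's own unit tests use smaller fleets and schedules.
These sizes give posterior medians of the transit-state persistence
stable to within a few hundredths across seeds, which is the tolerance
the recovery checks use. The full classical schedule (2 × 180,000,
burn-in 100,000, thin 40, retaining exactly 4,000 samples) is
configuration like any other and is exercised arithmetically in the
suite.

Degenerate inputs are handled conservatively: segments spanning less
than one grid step are rejected with a logged reason; constant
covariates and constant feature columns are rejected by name; empty
location sets propagate as empty results, not errors, where a
downstream stage can still proceed.

## Known limitations

* The observation-error scales are assumed known; misspecifying them
  biases $\gamma$ (too-large scales let the smoother over-straighten
  paths, deflating the transit estimate).
* Fully pooled movement parameters understate between-individual
  variability; the posterior intervals are accordingly optimistic.
* Single-site location updates mix slowly if the process noise is tiny
  relative to observation error; the adaptive proposals mitigate but do
  not remove this.
* The Rayleigh p-value approximation is accurate for n ≥ ~10; for the
  3–15 departing individuals typical of a field season it is adequate
  but not exact.
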