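---
title: "From Argos fixes to habitat maps: the pengdisp pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From Argos fixes to habitat maps: the pengdisp pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pengdisp)
```

## The scientific problem

Juvenile king penguins disperse from their natal colony within days of
fledging and spend months at sea before transmitters fail or fall off.
`pengdisp` implements the analysis chain such a telemetry study needs:

1. **Track processing** — reduce duty-cycled Argos fixes to one "daily
   position" per bird per duty cycle and compute migratory parameters.
2. **Environmental gridding** — put candidate covariates on a regular
   lon/lat lattice, derive local-heterogeneity gradients, standardize, and
   screen collinearity.
3. **Occurrence building** — turn in-window daily positions into presence
   cells and draw masked pseudo-absence sets.
4. **Habitat modelling** — a replicated, balanced binomial-GLM ensemble
   with backward-forward stepwise AIC selection, competing-model tables,
   Akaike weights and AUC cross-validation.
5. **Mapping** — project a selected model into a categorized
   habitat-probability surface.

A synthetic-data module generates tracks and environments with *known*
habitat preferences, so every stage can be validated against ground truth.

## Track processing

Argos location classes 0–3 correspond to positional accuracies of >1 km,
<1 km, <350 m and <150 m. With a 4 h on / 20 h off transmitter duty cycle
(switched on at 01:00 GMT) a bird yields a cluster of fixes once per day;
`select_daily_positions()` keeps the highest-class fix per bird per cycle,
breaking ties by the earlier timestamp. A duty cycle is the 24 h window
opening at the switch-on hour, so a fix at 00:30 GMT belongs to the
previous day's cycle.

From the daily positions, `migration_summary()` computes, per bird:

* **duration** — whole days from the deployment date to the last
  transmission. This convention reproduces the published per-bird
  durations of the 2007 cohort exactly (see `migration_parameters()` and
  the acceptance tests); measuring from the departure date does not.
* **maximum distance to the colony** — the furthest great-circle
  displacement from the natal site;
* **minimum distance covered** — the sum of great-circle distances between
  consecutive daily positions, a lower bound on the true path length;
* **mean / sd / max daily distance** — statistics of the consecutive
  segments. When daily positions are missing, a segment spans more than one
  day; segments are used as-is and the number of such gap segments is
  reported (`n_gap_segments`) rather than silently rescaled.

Distances use the haversine formula on a 6371 km sphere
(`great_circle_km()`, via the geosphere package); its error is orders of
magnitude below the Argos positional error. Cohort statistics
(`cohort_stats()`) use arithmetic means and the sample (n−1) standard
deviation; a single-bird group reports `NA`, not 0.

The fieldwork anchor dates are 11 December 2007 (Falkland Islands) and
13 December 2007 (South Georgia); fieldwork at the latter spanned two days,
and 13 December is the date that reproduces all eight published South
Georgia durations.

## The analysis grid

`make_grid()` builds the lattice from its bounds; the study default is
10°W–110°W × 40°S–75°S at 0.04° (a ~4 km² cell at these latitudes), giving
2500 × 875 cells. Cells are indexed row-major from the north-west corner
and boxes are half-open (west and north edges closed), so a point on an
interior edge belongs to exactly one cell. `aggregate_to_grid()` averages
the source pixels whose centres fall in each cell; a cell with no
(non-missing) source pixels stays missing.

### Gradients

Local heterogeneity of a covariate is summarised by the proportional
change within the 3×3-cell moving window,

$$\mathrm{PC} = \frac{(\max - \min) \times 100}{\max},$$

computed by `gradient_pc()` on the *raw* (unstandardized) layer. Choices
worth stating:

* The window is 3×3 **cells** of the analysis grid. (At 0.04° that is a
  0.12° window, not 0.75°; the cell-count definition is the one the PC
  formula is stated for, and is what this package implements.)
* Edge cells use the truncated neighbourhood — no padding is invented.
* Degenerate cases: constant neighbourhood → 0; all-zero neighbourhood →
  0 by convention; negative inputs are an error, since PC is not
  meaningful across a sign change (all candidate variables here are
  non-negative; bathymetry is represented as positive depth, 0–7958 m).
* PC is invariant to positive rescaling of the layer, which the tests
  exploit.

### Standardization and screening

All eight covariates — BAT, CHLa, SST, SSH and their gradients BAT.G3,
CHLa.G3, SST.G3, SSH.G3 — are standardized to mean 0, sd 1 (n−1) before
modelling; gradients are standardized together with everything else even
though they are already percentages, so that coefficients are comparable.
`spearman_screen()` reports all pairwise Spearman rank correlations and
flags |rs| > 0.5. The screen is diagnostic only: no variable is dropped
automatically, because stepwise selection below operates on the full
candidate set and the flag is information for the analyst.

## Occurrence data

Only daily positions between 1 January and 31 March 2008 enter the
habitat models (the default window of `rasterize_presence()`): earlier
positions are dominated by the colony's immediate surroundings, later ones
are too sparse after transmitter failures. Presence is binary per cell
over the whole window — a cell is a presence if at least one in-window
daily position falls in it.

Pseudo-absences are drawn uniformly without replacement from the
*candidate background*: cells with complete environmental data that are
neither presences nor inside the 3×3 mask around any presence
(`presence_mask()`). "Surveyed area" is operationalized as data-complete
cells, since no survey polygon exists and incomplete cells could not be
modelled anyway. Each of the (default 100) sets has exactly as many cells
as there are presences, and sets are drawn independently of each other.
No extra buffer is applied around the colony beyond the presence mask.

## The replicate GLM ensemble

Each replicate `r` of `run_replicates()`:

1. combines the fixed presence cells with pseudo-absence set `r`
   (balanced design, prevalence 0.5);
2. draws a stratified 70/30 train/test partition of each class — a
   without-replacement partition, so train and test are disjoint;
3. runs backward-forward stepwise AIC from the full 8-term model on the
   training data (`stepwise_aic()`): at each step the single-term deletion
   or addition that most decreases AIC is applied, until no move decreases
   it; ties go to the smaller model, then lexicographic order;
4. computes the selected model's AUC (rank-based Mann–Whitney, ties 1/2)
   on the held-out 30%.

The candidate set is the 8 main effects only — no interactions or
polynomial terms. Replicates whose selected fit does not converge or shows
complete separation are excluded from summaries and counted; silently
including them would corrupt the AUC mean. The ensemble summary reports
the mean AUC ± its standard error over successful replicates, per-term
selection frequencies and signs,
and the usability flag (mean AUC ≥ 0.7).

`competing_models()` refits every model evaluated during a search on the
same data, keeps those within ΔAIC ≤ 2 of the best, and reports them
best-first with Akaike weights $w_i = e^{-\Delta_i/2} / \sum_j
e^{-\Delta_j/2}$ normalized over the retained set. The stepwise search
path, not an exhaustive all-subsets enumeration, defines the model pool —
that is what "candidate models" means here, and it is why the in-package
stepwise implementation records every evaluated candidate (`$path`)
rather than delegating to `stats::step()`, which keeps only the accepted
moves. `stats::step()` serves as an independent cross-check in the tests.

## Mapping

`predict_map()` evaluates the inverse-logit of the selected model's linear
predictor in every cell. Cells with any missing covariate, or outside the
per-covariate `[train min, train max]` envelope (`train_envelope()`), are
masked — they are outside the model's environmental space, and the simple
min–max box is the most transparent operationalization of that idea. The
mapped model is, by default, the most-parsimonious specification refit on
all presences plus pseudo-absence set 1; an ensemble-mean surface can be
assembled from the replicate coefficients if wanted.

`categorize_map()` cuts probabilities into low (< 0.33), medium
(0.33–0.66, both endpoints included, as the class labels are printed) and
high (> 0.66). Maps are exported as plain-text ESRI ASCII grids
(`export_map()`, `write_ascii_grid()`), with 17-significant-digit values
so a write/read round trip is bit-exact; the category raster encodes
masked/low/medium/high as 255/0/1/2.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated:

* **Environmental fields** — Gaussian white noise kernel-smoothed to a
  correlation length (in cells) and linearly rescaled into each variable's
  range: BAT 0–7958 m, CHLa 0–24.91 mg m⁻³, SST 0–21.32 °C, SSH
  46.30–51.29 cm. Rescaling guarantees range conservation; smoothness 0
  gives white noise. Fields are generated independently per variable and
  month.
* **Movement** — a biased correlated random walk at the daily-step
  granularity of the migratory statistics: lognormal step lengths with
  mean 45 km and sd 25 km (the cohort's observed daily-distance scale),
  candidate headings persistent around the previous heading
  (`turn_concentration`, circular sd `1/sqrt(kappa)`), destination chosen
  with weight `exp(habitat_bias × suitability)`. No behavioural claim is
  attached to this form — it is a stand-in that produces
  habitat-associated, autocorrelated tracks.
* **Observation** — per day, `1 + Poisson(2)` fixes at uniform times in
  the 01:00–05:00 GMT on-window; classes drawn from the mix
  (0.088, 0.300, 0.350, 0.262) for classes 0–3, chosen so that the best
  fix of a day is class ≥ 1 about 98.6 % of the time, matching the
  reported share of daily positions accurate to 1 km or better; positional
  noise is bivariate Gaussian with RMS displacement equal to the class
  error scale (1.5, 1.0, 0.35, 0.15 km).
* **Occupancy ground truth** — a logistic model on the standardized
  covariates (`habitat_model()`), the generative counterpart of the GLM
  fitted downstream. `calibrate_intercept()` sets the intercept so the
  expected number of occupied cells matches a target, and
  `sample_presence_cells()` draws cell occupancy Bernoulli(p).

What the generator does **not** emulate: land and coastlines (the grid is
treated as all-ocean, since the analysis only ever uses cells with
complete environmental data), ocean fronts and circulation, sea-ice
dynamics, cross-correlated covariates, energetics or mortality. Passing
the recovery tests therefore shows the *inferential machinery* is sound —
it does not show that real tracks meet the model's assumptions
(independence of cells, correctly specified main-effects logit).

## Validation design and problem sizes

The package's acceptance suite validates four things, at sizes chosen to
keep the full suite comfortably desk-scale:

* **Published durations** — the per-bird tracking durations recompute
  exactly from the published deployment/end dates (totals 1066 FI,
  1045 SG, 2111 overall; means 107, 131, 117 ± 58 days).
* **Formula oracles** — `gradient_pc()` against a brute-force per-cell
  loop, `auc()` against exhaustive pair counting, `akaike_weights()`
  against the closed form, and the GLM log-likelihood against a
  hand-computed Bernoulli sum.
* **Parameter recovery** — a 125 × 125 grid (10° × 10° at 0.08°),
  smoothness 4 cells, true preferences BAT +1, SST −1, CHLa +1 at |β| = 1,
  intercept calibrated to an expected 600 presences, 100 pseudo-absence
  sets, 100 replicates. The ensemble must select all three true terms with
  correct signs in ≥ 90/100 replicates at mean AUC ≥ 0.7, and a
  label-shuffled null must give mean AUC within 0.5 ± 0.03. With |β| = 1
  and ~600 presences the true-term Wald statistics are ≈ 10, so recovery
  is expected to be near-certain; the criterion guards against regressions
  in the selection/validation plumbing, not against statistical bad luck.
* **Determinism** — the whole pipeline, from field generation through
  mapping, is bit-identical under a repeated seed, and no pseudo-absence
  set ever intersects a presence or its 3×3 mask (checked exhaustively).

`scripts/acceptance.R` reruns the recovery study and the track/observation
simulation from scratch at these sizes and writes the resulting quantities
as JSON.

## Known limitations

* Spatial autocorrelation of residuals is not modelled; presence cells
  from a single animal's track are not independent, and the GLM treats
  them as if they were (as does the design this package implements).
* The stepwise/AIC pool is the search path, so models never visited by
  the search cannot appear in the competing-model table.
* The environmental-space mask is an axis-aligned box; cells inside the
  box but outside the joint training cloud are still predicted.
* Only geographic lon/lat grids are supported — no projections.
* The ASCII-grid reader/writer covers the formats this pipeline needs; it
  is not a general raster IO layer.
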