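# pengdisp

Post-fledging dispersal tracking and habitat modelling for juvenile
penguins.

`pengdisp` is an R package for movement ecologists analysing satellite
telemetry of juvenile penguins (and similar duty-cycled Argos datasets):
it takes raw Argos fixes to per-bird migratory statistics, and takes
gridded environmental covariates plus at-sea positions to a replicated
presence/pseudo-absence habitat model and a categorized
habitat-probability map. A synthetic-data module simulates environments,
habitat-biased tracks and Argos-like observations with known ground truth,
so the whole pipeline is testable end to end without any external data.

## The model at the core

Cell occupancy on a 0.04° analysis grid is modelled as a binomial GLM with
a logit link on eight standardized covariates — bathymetry (BAT),
chlorophyll-a (CHLa), sea surface temperature (SST), sea surface height
(SSH) and their 3×3 moving-window proportional-change gradients
(`*.G3`, with PC = (max − min) × 100 / max):

```
logit P(presence) = β₀ + β₁·BAT + β₂·BAT.G3 + … + β₈·SSH.G3
```

Presences are the grid cells holding at least one filtered daily position
in the modelling window; pseudo-absences are drawn equal-n from
data-complete cells outside the 3×3 mask around every presence. The model
is fit 100 times — each replicate pairing the presences with a fresh
pseudo-absence set and a stratified 70/30 train/test split — with
backward-forward stepwise AIC selection from the full model. Competing
models (ΔAIC ≤ 2) are reported with Akaike weights
w_i = exp(−Δ_i/2) / Σ exp(−Δ_j/2), predictive power as the mean
rank-based ROC AUC over the 100 held-out sets (usable if ≥ 0.7), and the
selected model is projected over the grid, masking cells outside the
training min–max environmental envelope, into low / medium / high classes
(< 0.33 / 0.33–0.66 / > 0.66).

## Worked example

Simulate a small study with known preferences (BAT +1, SST −1, CHLa +1 on
standardized covariates), process the tracks, and fit the ensemble:

```r
library(pengdisp)

grid  <- make_grid(-70, -60, -60, -50, cell_deg = 0.08)
stack <- make_synthetic_stack(grid, seed = 7)
truth <- calibrate_intercept(habitat_model(c(BAT = 1, SST = -1, CHLa = 1)),
                             stack, target_presences = 600)

# --- tracks: 8 birds, 110 days, Argos-observed -------------------------
colonies <- data.frame(name = "COL", lon = -65, lat = -55,
                       deployment_date = as.Date("2007-12-11"), n_birds = 8)
sim   <- simulate_dispersal_study(sim_config(step_km_mean = 15, step_km_sd = 6),
                                  stack, truth, colonies, n_days = 110, seed = 8)
daily <- select_daily_positions(sim$fixes)
summaries <- do.call(rbind, lapply(split(daily, daily$bird_id), function(d)
  migration_summary(d, colony_lon = -65, colony_lat = -55,
                    deployment_date = "2007-12-11", colony = "COL")))
cohort_stats(summaries, group = "all")[, c("n_birds", "total_duration_days",
             "mean_duration_days", "mean_max_distance_colony_km")]
#>   n_birds total_duration_days mean_duration_days mean_max_distance_colony_km
#> 1       8                 880                110                       449.7

# --- habitat model: presences from the known occupancy model -----------
pres <- presence_set(sample_presence_cells(truth, stack, seed = 9))
pa   <- sample_pseudo_absences(pres, env_complete_cells(stack), grid,
                               n_sets = 100, seed = 10)
ens  <- run_replicates(pres, pa, stack, n_rep = 100, seed = 11)
ens
#> replicate_ensemble: 100/100 replicates converged; mean AUC 0.913 +/- 0.001 (SE) [usable]
#>   selection frequencies: BAT 100, CHLa 100, SST 100, BAT.G3 49, CHLa.G3 16, SSH 14, SSH.G3 9, SST.G3 4

df <- cbind(occ = c(rep(1, length(pres$cells)), rep(0, pa$n_presences)),
            stack_values_at(stack, c(pres$cells, pa$sets[[1]])))
sw <- stepwise_aic(df, canonical_terms())
competing_models(sw, df)[, c("formula_signed", "aic", "delta_aic", "akaike_weight")]
#>                             formula_signed   aic delta_aic akaike_weight
#> 1          +BAT +BAT.G3 +CHLa +SSH.G3 -SST 858.0     0.000        0.4697
#> 2     +BAT +BAT.G3 +CHLa -SSH +SSH.G3 -SST 859.9     1.875        0.1839
#> 3  +BAT +BAT.G3 +CHLa +SSH.G3 -SST +SST.G3 860.0     1.992        0.1735
#> 4 +BAT +BAT.G3 +CHLa +CHLa.G3 +SSH.G3 -SST 860.0     1.999        0.1729

envlp <- train_envelope(stack, c(pres$cells, pa$sets[[1]]), sw$best_terms)
map   <- categorize_map(predict_map(sw$best_fit, stack, envelope = envlp))
table(factor(map$category, 0:2, c("low", "medium", "high")))
#>    low medium   high
#>   9448   2918   3101
```

All three true preferences (deeper water +BAT, higher chlorophyll +CHLa,
colder water −SST) are selected in every replicate with the correct signs;
every competing model contains them; the mean held-out AUC of 0.91 marks
the ensemble as usable; and `export_map(map, "habitat")` writes the
probability and three-class surfaces as plain-text ESRI ASCII grids.

The published migratory parameter table of the 2007 two-colony cohort
ships with the package (`migration_parameters()`), and `cohort_stats()`
on it reproduces the printed totals and means (1066 + 1045 = 2111
tracking days; 117 ± 58 days overall).

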