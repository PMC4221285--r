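# avirange

Presence-only species distribution modelling with an L1-regularized
maximum-entropy (maxent) model, and attribution of contemporary and
projected range to climate versus land-use/land-cover (LULC) change.

`avirange` is aimed at spatial ecologists who want a fully scriptable,
dependency-light R implementation of the classic presence-only workflow:
filter citizen-science occurrence records (observation-protocol limits,
breeding-season window, spatial thinning), build a 14-layer predictor stack
(focal LULC class counts and diversity, ensemble climate means, elevation /
slope / compound topographic index), fit a maxent model, evaluate it
(ROC/AUC, maximum-sensitivity-plus-specificity threshold), and run a
twelve-simulation design that isolates the effect of projected climate
change versus projected LULC change on species range.  A synthetic-world
generator supplies landscapes, emissions-scenario futures and virtual
species with *known* suitability, so every stage is testable against ground
truth without any external data.

## The model

Maxent fits the Gibbs density over a background sample,

    q(x) = exp(eta(x)) / Z,    eta(x) = sum_j lambda_j f_j(x),

by minimizing the penalized objective

    J(lambda) = -mean_presence eta + log Z + sum_j beta_j |lambda_j|,

with features f_j in [0,1] (linear, quadratic, product, hinge, threshold,
activated by presence sample size), per-feature penalties
`beta_j = Lambda(class, m) * sd_j / sqrt(m)`, and sequential coordinate
descent (best single-feature update per iteration, closed-form
bound-minimizing step).  Projection onto future conditions clamps covariates
to the training range.  The logistic output `e^H q / (1 + e^H q)` (H the
entropy of the fitted density) maps suitability to (0,1) with a null model
at exactly 0.5.  Binary range maps use the threshold maximizing
sensitivity + specificity; net range change is the percent change in
suitable cells relative to the contemporary full-model range.

## Worked example

Simulate a world, sample a virtual forest species, filter the records, and
run the attribution design for one scenario:

```r
library(avirange)

world    <- generate_landscape(landscape_config(seed = 11))
species  <- virtual_species(temp_optimum = 9, temp_tolerance = 2.5,
                            preferred_lulc_class = 6L)  # a cool forest bird
records  <- sample_presences(world, species, n_raw = 2000, seed = 12)
filtered <- filter_presences(records, min_dist_km = 1, seed = 13)
filter_log(filtered)
#>   stage        n
#> 1 original  2000
#> 2 protocol  1761
#> 3 season     681
#> 4 thin       425

future <- apply_scenario(world, scenario_preset("A2", seed = 14))
runs   <- run_design(filtered, world, list(A2 = future),
                     design = build_design("A2"), seed = 15)
runs$results[, c("run_id", "epoch", "config", "scenario", "auc_test",
                 "area_extent_pct", "net_change_pct")]
#>   run_id epoch        config    scenario auc_test area_extent_pct net_change_pct
#> 1      1 contemporary all       <NA>        0.576            41.7          NA
#> 2      2 contemporary climate_… <NA>        0.559            46.8          NA
#> 3      3 contemporary lulc_no_… <NA>        0.536            30.1          NA
#> 4      4 future       both_cha… A2         NA                17.6         -57.7
#> 5      5 future       climate_… A2         NA                17.1         -59.0
#> 6      6 future       lulc_cha… A2         NA                44.6           7.05
```

Reading the result: the strongly warming A2-like future removes 59% of the
modelled range when only climate changes (run 5), while LULC change alone
shifts it by +7% (run 6); the combined projection (run 4) is dominated by
the climate signal.  Test AUCs are modest here because spatial thinning on
the small demo world flattens record density — the cost of bias correction.
The fitted contemporary model attributes most of its training gain to the
two covariates the species truly responds to:

```r
percent_contribution(runs$models[["1"]])
#>    variable     category   contribution_pct
#>  1 avg_temp     climate               29.5
#>  2 forest_count lulc                  23.2
#>  3 avg_precip   climate                6.37
#>  4 cti          topography            6.15
#>  5 hay_count    lulc                  6.10
#>  # ... 9 more rows
```

`run_pipeline(demo_config())` chains the whole thing (simulation → filters →
covariates → fits → evaluation → attribution → class summaries) for three
virtual species and three scenarios, reproducibly from one master seed.
`tidy()`/`glance()` expose fitted models broom-style; `autoplot()` and
`plot_contributions()` / `plot_net_change()` / `plot_auc()` give ggplot
views of rasters and results.

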