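# nichetrack

Species distribution modeling with a maximum-entropy core, built for
reproducible range-change analysis. `nichetrack` is aimed at ecologists who
model where a species can live from presence-only records — museum and
herbarium occurrences contrasted against gridded environmental layers — and
who need the downstream products conservation studies actually report:
habitat-suitability classes, per-scenario areas and percent changes,
expansion/contraction maps, and the migration track of the suitable-habitat
centroid across climate scenarios.

## The model

For presences $x_1,\dots,x_m$ and background cells $b_1,\dots,b_B$, the
suitability model is the Gibbs density
$q_\lambda(x) = \exp(\lambda\cdot f(x))/Z_\lambda$ over the background, with
$f$ a feature expansion (linear, quadratic, hinge, optionally product and
threshold) of the environmental covariates. The weights minimize

$$-\tfrac{1}{m}\textstyle\sum_i \lambda\cdot f(x_i)
  + \log \tfrac{1}{B}\textstyle\sum_j e^{\lambda\cdot f(b_j)}
  + \textstyle\sum_k \beta_k |\lambda_k|,
  \qquad \beta_k = \beta_{\text{mult}}\, s_k/\sqrt{m},$$

i.e. the maximum-entropy distribution whose feature expectations match the
presence means within L1 tolerances — solved by compiled coordinate descent
with an active set. Suitability in $[0,1]$ comes from the cloglog transform
$1 - \exp(-e^H q_\lambda)$ (logistic and raw are selectable). Evaluation is
seeded k-fold cross-validation with rank-based AUC; variable diagnostics are
percent contribution, permutation importance, jackknife gains and response
curves.

Everything around the core is a tidy pipeline: occurrence cleaning and 2.5′
spatial thinning, Pearson-correlation pruning at |r| ≥ 0.8 (keeping the
higher-contribution member), clamped projection onto scenario stacks,
four-band classification (0.25/0.5/0.75), geodesic areas in 10⁴ km², percent
changes versus a baseline, change maps, and haversine centroid tracks. A
seeded synthetic-scenario generator (`generator_config()`,
`end_to_end_fixture()`) stands in for the climate/soil downloads of a real
study so the whole pipeline is testable offline with known ground truth.

## Worked example

Simulate a study system, select variables, fit with 10-fold cross-validation,
and project a drier future (the dominant driver shifted down one standard
deviation):

```r
library(nichetrack)

cfg  <- generator_config(seed = 1)                    # 100x100 grid, 6 vars
st   <- gen_env_stack(cfg)
occ  <- sample_presences(true_suitability(st, cfg), 200, seed = 2)
pres <- extract_at_points(occ, st) |> dplyr::filter(!nodata)
bg   <- sample_background(st, 10000, seed = 3)

sel <- select_variables(pres, st, maxent_params(seed = 3))
sel$drop_log
#>   kept     dropped     r contribution_kept contribution_dropped
#> 1 alum_sat dem     0.907             0.627               0.0159

cv <- maxent_cv(pres[, sel$kept], bg[, sel$kept],
                maxent_params(seed = 4), stack = st)
glance(cv)
#>   folds mean_test_auc sd_test_auc mean_train_auc mean_gain
#> 1    10         0.949      0.0118          0.953      2.05
classify_auc(glance(cv)$mean_test_auc)
#> [1] "very_high"
```

The planted r = 0.9 duplicate pair was pruned to its informative member, and
the held-out AUC of 0.949 lands in the "very high" accuracy band. The
dominant simulated driver tops the contribution table:

```r
fit <- maxent_fit(pres[, sel$kept], bg[, sel$kept], maxent_params())
percent_contribution(fit)
#>   variable contribution
#> 1 bio14          89.5
#> 2 bio12           5.73
#> 3 bio4            2.84
#> ...
```

Classify, account, and track the centroid:

```r
fut    <- gen_scenario(st, c(bio14 = -1))
cm_now <- classify_suitability(cv$mean_raster)
cm_fut <- classify_suitability(predict(cv, fut))
rep    <- scenario_report(list(current = cm_now, future = cm_fut), "current")

rep$areas
#>   scenario area_high ratio_high area_total_suitable ratio_total_suitable
#> 1  current   0.79720         NA              3.3317                   NA
#> 2   future   0.06855      -91.4              0.5676               -82.96
rep$centroids
#>   scenario     lon     lat displacement_km bearing_deg
#> 1  current 107.364 24.3919              NA          NA
#> 2   future 107.251 23.9485         50.6209    -166.823
```

Areas are 10⁴ km²; the drier scenario contracts total suitable habitat by
83% (high-suitability habitat by 91%) and moves the habitat centroid about
51 km south-southwest. `autoplot()` methods exist for rasters, response
curves and centroid tracks, and `run_full(config)` executes the whole
pipeline from a YAML config with byte-identical reruns under a fixed seed
(see `inst/cli/nichetrack` for a shell entry point).

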