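# reefshift

Quaternary glacial cycles repeatedly destroyed and rebuilt shallow
coral-reef habitat: sea level fell by on the order of 120 m, exposing reef
shelves, while cooler seas pushed reef-forming conditions toward the
equator. Species that could not keep recolonizing the habitat that
reappeared after each glacial maximum still carry that history in their
present-day ranges. `reefshift` is an R package for macroecologists that
quantifies this historical signal in reef-fish distributions and asks which
life-history traits predict it.

The pipeline:

1. **Paleo-habitat reconstruction** — sediment-core SST and sea-level
   series are regridded to a common 1,000-year timeline, converted to
   cross-core mean anomalies against a pre-warming baseline SST map, and
   combined with bathymetry to yield boolean reef-suitability grids per
   timestep under a sweep of thermal thresholds (23–28 °C): a cell is
   suitable when immerged, within 0–100 m of contemporaneous water depth,
   and warm enough.
2. **Isolation from stable areas (IREF)** — per timestep, the least-cost
   distance from every cell to the nearest suitable cell over the
   8-connected sea graph (land is a barrier; steps cost great-circle km).
   IREF = (sum of distances over timesteps) / (number of timesteps the cell
   itself was suitable); 0 in permanent refugia, large where habitat
   collapsed often and refugia were far.
3. **Species distribution models** — per species, logistic GLMs with linear
   and quadratic terms: logit P(pres) = α + Σ_k (β_k1 x_k + β_k2 x_k²) over
   contemporary predictors (SST, CHL, O2, NI, SSS) and IREF. Deviance
   explained D² = 1 − SS_res/SS_tot is partitioned into pure contemporary,
   shared, pure historical (c = D²_full − D²_contemp) and unexplained
   fractions; models are validated by 100× repeated 70/30 split-sample AUC
   and Moran's I of residuals.
4. **Trait analysis** — the pure-historical fraction is related to body
   size, mobility and habitat specialization by all-subsets linear models
   with Akaike-weight importance (w_AIC) and model-averaged slopes, by PGLS
   with ML-estimated Pagel's λ, and by quantile regression (q = 0.75, 0.9)
   tracking the triangular size–history envelope.
5. **Assemblage mapping** — per-cell means of the historical fraction and
   body size over occupant species, and their cross-cell regression.

Because the underlying occurrence compilation is not redistributable, the
package ships a synthetic-world generator (`generate_world()`) that
reproduces the statistical structure the analysis assumes — glacial
cyclicity, bathymetry, correlated predictor fields, size/mobility-dependent
colonization lags, a phylogeny with Brownian signal in body size — together
with the ground-truth coefficients needed for parameter-recovery tests.

## Worked example

```r
library(reefshift)

cfg <- scenario_config(seed = 7, n_species = 60, grid_nrow = 48,
                       grid_ncol = 96, n_timesteps = 40, lag_strength = 2)
world <- generate_world(cfg)
study <- run_study(world, n_auc_repeats = 25, n_boot = 100)
print(study)
```

```
reef_study
  threshold sweep peak: 27 degC (historical-only mean D2)
  species retained: 60 (of which 60 converged)
  mean D2 full/contemporary/historical: 0.354 / 0.326 / 0.070
  averaged size slope: -0.0001; PGLS lambda: 0.091
  assemblage size-history: slope -0.0002756, R2 0.530, t -12.01
```

Reading the output: the threshold sweep recovers the 27 °C value used to
generate the world (mean historical-only D² peaks there). Adding IREF
raises mean explained deviance from 0.326 to 0.354; the historical-only
model explains 0.070 on its own. The model-averaged slope of the
pure-historical fraction on body size is negative — smaller fish carry more
of the historical signal — and cell assemblages follow suit: cells whose
occupants have a high mean historical fraction have smaller mean body size
(negative slope, t = −12.0, R² = 0.53). `study$sdm` holds the per-species table
(coefficients, D² variants, deviance fractions a–d, AUC mean/sd, Moran's
I); `study$trait_models`, `study$pgls_size`, `study$quantile_slopes` and
`study$assemblage` hold the downstream analyses.

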