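---
title: "Methods: reconstructing Quaternary reef habitat and its signal in fish distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing Quaternary reef habitat and its signal in fish distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Glacial–interglacial cycles repeatedly destroyed and rebuilt shallow
coral-reef habitat: low sea stands exposed shelves (sea level fell on the
order of 120 m) while cooling pushed reef-forming conditions toward the
equator. If a fish species failed to recolonize habitat that became suitable
again after a glacial period, its present-day range still carries that
historical imprint. `reefshift` implements a pipeline that quantifies this
imprint per species and asks which life-history traits (body size, mobility,
habitat specialization) predict it.

## Pipeline and models

**Paleo-habitat reconstruction.** Sediment-core SST and sea-level series are
linearly interpolated onto a common 1,000-year age grid (the regridding rule
is a package choice; cores are cross-correlated as a consistency check). The
per-timestep SST anomaly — core SST minus the pre-warming baseline SST at the
core's cell — is averaged across cores and applied to the baseline map as a
single basin-wide additive shift; no spatial interpolation between cores is
attempted, so the spatial pattern of the hindcast is that of the baseline.
A cell is reef habitat at time *t* when it is immerged (elevation below the
contemporaneous sea level), lies within the reef depth window (default 0–100
m below contemporaneous sea level, since reef growth is confined to roughly
the top 100 m; the minimum-depth bound is exposed but defaults to 0), and
the hindcast SST meets a thermal threshold. Thresholds are swept over
23–28 °C; stacks at higher thresholds are strict subsets of those at lower
ones, which the tests assert.

**Isolation from stable areas (IREF).** For each timestep the least-cost
distance from every cell to the nearest contemporaneously suitable cell is
computed on the 8-connected sea graph, with great-circle step costs and the
contemporaneous land mask as barrier (low stands both remove habitat and
create barriers). Summing distances over timesteps (C) and dividing by the
number of timesteps the cell itself was suitable (K) gives IREF = C / K,
defined where K > 0. IREF is 0 exactly in always-suitable refugia and grows
with frequent local collapse far from refugia. Two policies are needed where
the definition is silent: timesteps with no suitable habitat anywhere are
skipped (and counted) rather than given an arbitrary distance, and sea cells
disconnected from all suitable habitat at a timestep contribute a capped
penalty equal to the grid-diagonal geodesic instead of infinity, so
downstream regressions keep finite predictors. Distances are computed at the
fine grid and block-averaged to the analysis grid afterwards.

**Species distribution models.** Each species' presence/absence over
analysis cells is modelled by logistic regression with linear and quadratic
terms in the z-scored predictors (SST, CHL, O2, NI, SSS contemporarily;
IREF historically). Deviance explained is D² = 1 − residual/null deviance.
Fitting the full, contemporary-only and historical-only models partitions
deviance into pure contemporary (a = D²~full~ − D²~hist~), shared
(b = D²~contemp~ + D²~hist~ − D²~full~), pure historical
(c = D²~full~ − D²~contemp~) and unexplained (d = 1 − D²~full~); the four
fractions close to 1 by construction and tiny negative values (numerical
noise) are clamped. Predictors are z-scored before expansion — a
conditioning choice that leaves D² invariant. Species with fewer than 10
presence cells are dropped; an equal absence floor is added because a
species present everywhere is unidentifiable. Fits are flagged
non-converged on optimizer failure, non-finite coefficients, or any
standardized |coefficient| > 15 (quasi-separation), and excluded from
downstream summaries. Discrimination is measured by AUC under 100 stratified
70/30 split-sample repeats (rank/Mann–Whitney formulation with ties giving
0.5); residual spatial autocorrelation by Moran's I with row-standardized
queen weights on the analysis grid.

**Trait analysis.** The pure-historical fraction c is regressed on traits by
ordinary linear models over all 2³ subsets of {size, mobility,
specialization}. Akaike weights w = exp(−Δ/2)/Σexp(−Δ/2) give each trait a
relative importance (summed weight over models containing it) and
model-averaged slopes (conditional averaging over models containing the
term, with unconditional standard errors that add the between-model spread).
Mobility is dummy-coded against the "mobile within a reef" reference. The
phylogenetic check refits the size relation by GLS under
V(λ) = λ·V~BM~ + (1−λ)·diag(V~BM~), profiling Pagel's λ over [0, 1] by a
coarse grid plus local refinement (tolerance 1e−6); λ = 0 reproduces OLS
exactly, which the tests assert to 1e−8. Species missing from the tree can
be grafted onto a random congeneric tip at half its terminal branch, which
preserves ultrametricity. Because small species can carry either a strong or
a weak historical signal while large species carry only weak ones, the
size–history relation is triangular; quantile regressions at q = 0.75 and
0.9 track the declining upper envelope. The quantile fits minimize the check
loss exactly by enumerating the LP vertices (lines through point pairs),
with bootstrap standard errors; size enters in cm by default (a log10 option
exists).

**Assemblage mapping.** Per analysis cell, the unweighted mean of the
pure-historical fraction and of body size over occupant species; a
cross-cell OLS of mean history on mean size summarizes the geography (both
directions share R²; the stated direction's slope, t and p are reported).

## The synthetic world

Because the compiled occurrence database behind the original analysis is
not redistributable, all tests run on a generated world with known truth.
The generator emulates: glacial–interglacial cyclicity (sinusoid + AR(1)
noise in the cores; 20-ka period over 40 ka by default, a deliberately
compressed cycle that still gives two full habitat collapses), a 120 m
sea-level amplitude and 2.5 °C tropical SST amplitude (within the range of
late-Quaternary reconstructions, and small enough that the warmest
threshold never suffers basin-wide collapse), a smooth bathymetry with
~20 % land, a 30 % shallow shelf band and deep ocean, a latitudinal SST
gradient (30 °C equator, −0.35 °C per degree), and correlated smooth
contemporary predictor fields. Species presence/absence is sampled
cell-wise Bernoulli from a linear-quadratic logit whose IREF coefficient
magnitude rises stochastically with decreasing body size and mobility,
scaled by `lag_strength`; intercepts are solved so each species' expected
prevalence lands in (0.15, 0.6). Body size is log-uniform on 3–200 cm and
rank-matched to a Brownian trait evolved on a birth–death phylogeny, so
PGLS has real signal to remove. The parameter-recovery scenario uses
`lag_strength = 2`, which spreads true isolation effects over roughly 0–2
standard-deviation units of the linear predictor — a clear gradation against
estimation noise at ~250 cells.

What the world does *not* emulate: real coastline geometry, ocean
circulation, larval-dispersal kernels, spatial autocorrelation in
occupancy beyond what the smooth predictors induce (occurrences are
conditionally independent across cells, matching the SDM's own data model
and making parameter recovery well-posed), or observation error in the
occurrence data. Passing tests therefore demonstrate that the pipeline
recovers the structure it assumes — not that real reef-fish data satisfy
those assumptions.

## Numerical and design choices

- **Grids** are plain matrices with cell-center lon/lat vectors, rows
  north→south; serialized as CSV with JSON sidecars so every artifact is
  text. Aggregation is a block mean ignoring undefined cells.
- **Cost distances** use 8-connectivity with true geodesic diagonal costs
  (haversine, km); a unit-cost metric supports idealized lattices. The
  implementation is a super-source Dijkstra; tests compare it against an
  independent Bellman–Ford relaxation oracle on random grids.
- **Analysis cells** keep those with < 90 % land fraction whose aggregated
  IREF is defined (reef habitat existed at some timestep under the
  generating threshold); each sweep threshold then drops cells whose own
  IREF is undefined.
- **Threshold selection** takes the sweep maximum of mean historical-only
  D² across species.
- **Seeds**: every stage seed derives from one master seed by a stable
  string hash, so an entire study is bit-reproducible; the output manifest
  records MD5 checksums.
- **Problem sizes** in the tests — 200 species on ~250–280 cells for
  recovery, 120 species for trait replication, 50 for the threshold sweep,
  10 seeded replicates per stochastic claim — were chosen as the smallest
  scales at which the targeted effects are comfortably resolvable.
- **Multiple testing**: no correction is applied anywhere in the pipeline.

## Known limitations

Anomalies are basin-wide uniform shifts, so regional paleo-SST gradients are
not represented. The unreachable-cell cap and the collapse-skipping policy
are pragmatic completions of the IREF definition; both are recorded in the
isolation map's metadata. Conditional model averaging and the untransformed
(0–1 bounded) response in PGLS are defensible defaults with alternatives
(full averaging; logit transform) exposed as options. The quantile-slope
bootstrap assumes exchangeable species, ignoring phylogenetic dependence.
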