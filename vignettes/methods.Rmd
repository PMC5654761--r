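---
title: "Modelling zoonotic disease-emergence hotspots with reporting-effort correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling zoonotic disease-emergence hotspots with reporting-effort correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eidhotspots)
```

## The problem

Records of emerging infectious disease (EID) events — the documented first
appearance of a pathogen in people, through spillover from an animal
reservoir, a jump in incidence or range, or a change in virulence — are the
raw material for mapping where novel zoonoses are most likely to emerge.
Two features make these records awkward as a response variable:

* **Reporting bias.** An event is only recorded where someone is looking.
  Surveillance and biomedical publishing are concentrated in wealthy,
  urbanised regions, so the raw event map is as much a map of scientific
  attention as of biological risk.
* **Spatial uncertainty.** Events are geocoded with wildly uneven precision:
  some to exact coordinates (represented as a 5 km buffer), others only to a
  district, country, or continent-scale polygon.

`eidhotspots` implements a presence/background modelling pipeline that
addresses both: background samples are drawn proportional to a gridded
*reporting effort* surface (so the fitted response is risk *relative to*
attention), and every bootstrap replicate re-draws each event's location
from its uncertainty footprint (so location error propagates into every
downstream confidence band).

## The model

Work happens on an equal-angle longitude–latitude grid (`grid_spec`).
Each cell carries ~20 covariates in four groups: human activity (population,
cropland, pasture and their inter-decadal changes, urban land, managed
vegetation), hosts (mammal species richness, livestock and poultry
headcounts), environment (a scalar climate stratification, seven land-cover
percentages), and reporting effort. Covariates with temporal depth are
stored as decadal snapshots (1970, 1980, 1990, 2000); a sample from year
$y$ uses the nearest decade (years ending in 5 round up; 2001–2008 use the
2000 snapshot) and the change layer of the decade interval ending at that
snapshot (1970 borrows the 1970–1980 interval, since no earlier decade
exists).

One model replicate is built as follows:

1. Resample the $n$ events with replacement (bootstrap).
2. For each drawn event, draw one **presence** cell from its footprint and
   one **background** cell from all eligible land cells. Both draws are
   weighted by reporting effort in the *weighted* model; background draws
   are weighted by land area in the *unweighted* model (removing the
   latitude bias of equal-angle cells). Prevalence is thereby fixed at
   exactly 0.5.
3. Fit a boosted regression tree (BRT) classifier to the resulting
   $2n$-row design: Bernoulli deviance loss, depth-3 trees, small
   shrinkage, stagewise growth in steps of 35 trees, with the tree count
   chosen by internal $k$-fold cross-validation (the `gbm.step` recipe).

The ensemble (default 1000 replicates; 100 in the packaged simulation
studies) is aggregated into: a per-cell **mean response** map, per-predictor
**relative influence** distributions (share of total split-gain, summing to
100 within each replicate), and **partial dependence** bands (median and
empirical 90% interval of the replicate curves on a common probe grid
spanning the 10th–90th percentile of the pooled sampled values).

### The reporting-bias algebra

The weighted model's response $r$ is risk relative to effort $e$.
Multiplying back gives the **observed risk index** $r \times e$ — the risk
of an event being *observed* under current surveillance. Defining reporting
bias as $e / p$ (effort over human population $p$, taking
population-proportional effort as the surveillance optimum), the
**corrected risk index** is

$$ \text{corrected} = \text{observed} \times \frac{p}{e} \equiv r \times p, $$

an identity the package tests to $10^{-12}$. Cells whose effort falls at or
below the smoothing floor are masked rather than extrapolated. Maps are
rendered with standard-deviation scaling, the palette clipped 2.5 s.d.
either side of the mean.

### Reporting effort construction

The effort surface itself is built from a per-article toponym match table
(article id, coordinates, raw weight): weights are normalised within each
article (each article contributes total mass 1), summed to the grid, then
smoothed and imputed with a Poisson boosted-tree model on socioeconomic
covariates, since the raw surface is noisy and zero wherever the literature
happens to mention no place name. Text mining itself is outside this
package's scope: it consumes the match table as an input contract.
Predictions are floored at machine epsilon times the maximum rate so that
weighted sampling never divides by zero. Poisson-booster defaults: depth 3,
shrinkage 0.01, tree count by 5-fold CV deviance on a 25-tree grid.

## Validation

* `auc()` — rank-based probability that a presence outscores a background
  sample (ties credit 0.5); tested against exhaustive pair counting.
* `tss()` — maximum over thresholds of sensitivity + specificity − 1, with
  thresholds swept exhaustively at midpoints of adjacent unique scores
  (the printed statistic in the source analyses does not state whether the
  threshold was fixed or optimised; we optimise, and document it).
* `deviance_explained()` — $100(1 - D_{res}/D_{null})$ with the null at the
  observed prevalence. For a weighted model this is explicitly *relative to
  reporting effort*.
* `cross_validate()` — repeated 10-fold CV (study protocol: 100 rounds):
  per round one pair per event, pairs assigned to folds *together* so a
  pair never straddles train/test (the protocol's random assignment is
  ambiguous on this; keeping pairs together is the conservative choice and
  is configurable), each fold held out in turn, held-out predictions pooled
  into one AUC and TSS per round, summarised as median and empirical 90%
  interval. Validation absences may be re-drawn under a different null than
  training (evaluating the weighted model against an area-weighted null is
  the clearer contrast).

## The synthetic world

`gen_world()` builds a fully known study system so that every stage is
testable without the real (restricted) event geographies:

* **Predictors**: Gaussian-smoothed random fields (kernel radius 1.5 cells)
  on a 40 × 20 global grid with ~60% land, transformed to realistic units
  (log-normal population and headcounts, clipped percentage covers, a
  scalar climate index). Population, cropland, pasture and urban land get
  four decadal snapshots with smooth drift so change layers are
  non-trivial; urban land shares the population latent field decade by
  decade (target rank correlation 0.7).
* **True risk**: logistic in three standardised drivers — evergreen
  broadleaf trees (+1.2), mammal richness (+1.0), pasture change (+0.8) —
  mirroring the leading hypotheses (tropical forest, host biodiversity,
  agricultural change). The intercept (−2, mean cell risk ≈ 0.24)
  makes high-risk area a localised minority of land, which is what
  "hotspot" means: emergence is a rare event and its drivers concentrate
  risk in limited regions. A diffuse surface (intercept near 0) would make
  event locations nearly uninformative even for an oracle scoring rule.
* **Effort**: per-cell article intensity log-linear in standardised urban
  land (+1.2) and log population (+0.6) plus smooth noise; a synthetic
  match table is emitted and pushed through the *real* effort pipeline.
* **Events**: 147 cells (the size of the filtered wildlife-zoonosis
  record) drawn proportional to risk × effort^`bias_strength`
  (default 1: detection fully coupled to effort); half the events keep
  their exact cell, the rest get up-to-4×4 cell blocks, emulating
  municipal- to country-scale geocoding.

What the generator does *not* emulate: real geography and spatial
covariance between predictor families (its risk drivers are independent of
its effort drivers except through sampling), country borders, temporal
autocorrelation in event rates, or the heavy spatial clustering of real
surveillance. Passing recovery tests therefore demonstrates that the
machinery recovers known structure under honest noise — not that the real
drivers of emergence are identifiable from the real record.

## Numerical and design choices

* **Stagewise selection.** Because boosting is stagewise, models are
  trained in chunks and the CV deviance evaluated at every 35-tree prefix —
  numerically identical to literal 35-tree increments. Stopping: the run
  ends once the CV minimum has not improved for `patience` steps
  (default 3; the simulation studies use 4). A fit whose CV deviance never
  beats the null (2 log 2 at prevalence 0.5) is flagged a *null model*,
  predicts the prevalence, and is excluded (and counted) in ensembles.
* **Shrinkage vs step size.** The shrinkage must be small enough that the
  CV optimum is several steps in; at 0.05+ on these designs a single
  35-tree step overshoots the minimum entirely and the descent "fails" —
  the same coupling that motivated the original analyses' tuning. The
  1° study configuration (0.0035, 10 folds) is the default
  (`boost_config()`); the packaged simulation studies use
  `sim_boost_config()` (0.015, 5 folds, 32-bin histograms,
  bag fraction 0.75), under which a 100-replicate ensemble on the 40 × 20
  world fits in a few minutes on one core and selects 100–300 trees per
  replicate.
* **Probability clamping** at 1e-9 in deviance computations; internal CV
  folds stratified by label to preserve prevalence.
* **Degenerate inputs**: zero-variance layers scale to all-zeros in
  `sd_scale()`; all-zero effort footprints fall back to uniform presence
  draws; empty filter results warn rather than error; constant smoothing
  covariates fall back to a global mean Poisson rate.
* **Interchange formats** are plain text: long CSV for layers (lossless
  round-trip at full double precision), GeoJSON for events, CSV for match
  tables and score tables, JSON for summaries and manifests.

## Problem sizes in the packaged analyses

The numbered scripts under `analysis/` and the acceptance checks run the
full pipeline at simulation scale: 40 × 20 grid, 147 events, 100-replicate
ensembles, 10-round cross-validation, 10-seed recovery studies. These sizes
were chosen so the complete suite runs comfortably on a single core while
leaving every qualitative contrast (weighted vs unweighted, observed vs
corrected, null vs signal) clearly resolved; the machinery itself is
size-agnostic and accepts the 1° global grid and 1000-replicate, 100-round
study configuration unchanged.

## Known limitations

* The effort surface is only as good as the match table; the package
  deliberately does not model toponym extraction error.
* Population enters the correction as a multiplier and the model as a
  predictor; the deeper identifiability tangle between population, effort
  and urbanisation is acknowledged, not resolved — as in the source
  analyses.
* Footprint cells enter presence draws with effort weights but no
  within-polygon prior beyond effort; continent-scale footprints therefore
  contribute mostly uncertainty, which is the intended behaviour.
* TSS uses an optimised threshold; fixed-threshold TSS values are not
  comparable.
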