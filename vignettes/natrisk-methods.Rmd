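---
title: "natrisk: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{natrisk: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

`natrisk` estimates where alien ornamental plants — species cultivated in
gardens, already naturalized somewhere else in the world but not yet in
the study area — would find suitable climate today and under warming, and
where that climatic opportunity coincides with land actually available
for ornamental cultivation. The pipeline is an ensemble species
distribution modelling (SDM) protocol stacked into richness, hotspot and
risk maps, with a permutation test for the significance of mean range
change.

The core inference per species is presence-only SDM: occurrences on a
lon/lat grid are combined with pseudo-absences and six bioclimatic
predictors (temperature seasonality, maximum temperature of the warmest
month, minimum temperature of the coldest month, precipitation
seasonality, precipitation of the wettest and of the driest quarter).
Two model families are treated separately because their pseudo-absence
designs differ:

* **regression family** (GLM with linear + quadratic terms; GAM with
  thin-plate smooths): 10,000 pseudo-absences placed uniformly at random
  over the calibration extent, presence cells not excluded;
* **machine-learning family** (boosted regression trees; random forest):
  as many pseudo-absences as presences, drawn uniformly from cells whose
  centres lie > 200 km (great-circle) from every presence, re-drawn ten
  times to average out placement luck.

Case weights give presences and absences equal total mass (prevalence
0.5): presence weight 1, absence weight `n_pres / n_abs`. Models are
scored by the true skill statistic (TSS = sensitivity + specificity − 1)
on a three-times-repeated stratified 80/20 split. Models with TSS < 0.5
are dropped; each family's survivors are averaged on the probability
scale with weights proportional to raw TSS; each family ensemble is
binarized at the threshold maximizing TSS against the family's pooled
calibration data; and the final per-species map is the cellwise AND of
the two family maps — deliberately conservative, so suitable area is
under- rather than overestimated. Thresholds are never re-estimated for
future scenarios.

Downstream, binary consensus maps are stacked into per-cell richness;
hotspots are the top 10% of land cells by richness; hotspot change under
a scenario holds the current-climate cutoff fixed; risk = richness ×
available-area proportion (per land-cover weighting scheme, three
schemes); high-risk consensus = flagged by ≥ 2 of 3 schemes. Mean range
change per scenario is tested by a 1000-replicate sign-flip permutation
test on per-species suitable-cell counts, overall and per zonobiome of
origin (species assigned to several zonobiomes enter each subset).

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `cell_size` | 10 | arcmin | analysis resolution of the protocol (a 10′ cell at 50°N is ≈ 220 km²) |
| `min_occurrences` | 50 | cells | retention is strict `> 50` on deduplicated cells |
| `n_pseudo_random` | 10000 | cells | regression-family background size |
| `exclusion_radius_km` | 200 | km | ML-family pseudo-absence buffer |
| `pa_replicates` | 10 | draws | ML-family pseudo-absence repetitions |
| `calibration_fraction` | 0.8 | — | split-sample calibration share |
| `split_repeats` | 3 | — | split repetitions |
| `min_tss` | 0.5 | — | ensemble retention cutoff |
| `n_perm` | 1000 | — | permutation replicates |
| `hotspot_fraction` | 0.10 | — | top-cell share for hotspots/risk |
| learner block | see `default_learner_params()` | — | GAM k = 4; BRT 100 trees, depth 3, shrinkage 0.1; RF 100 trees, mtry 2 — conventional SDM settings, recorded with every model since the protocol itself fixes none |

All randomness flows from one `master_seed` through named substreams
(`seed_for(master, stage, species, replicate)`), so any sub-computation
reproduces in isolation and a full run is bit-reproducible from an
archived config.

# The synthetic world

`simulate_inputs()` replaces occurrence databases, gridded climatology
and land-cover products with generators whose statistical structure
matches what the analysis assumes:

* **Climate**: each layer is a fixed large-scale spatial pattern plus
  spatially autocorrelated noise (Gaussian-smoothed white noise,
  `noise_sd = 0.35` of the layer scale). The patterns are unit-variance
  shifted Legendre polynomials in the lon/lat fractions — mutually
  orthogonal under the uniform cell measure — because six *linear*
  gradients in two dimensions cannot keep all 15 pairwise |r| below 0.75
  (some pair is always within ~30° of parallel). Structural correlations
  are capped at 0.7 (the tmax–tmin pair, deliberately correlated as in
  real climates); the generator checks all pairwise Pearson correlations
  on land and retries with a perturbed seed until |r| < 0.75, mirroring
  the predictor screening applied to real bioclim sets.
* **Scenarios** are additive per-layer offsets ordered
  mild/intermediate/severe (RCP2.6/4.5/8.5): +1/+2/+4 °C on both
  temperature layers, growing seasonality, a drier dry quarter. Additivity
  is enough to create both range gainers and losers; no downscaling is
  emulated.
* **Species** have Gaussian product niches
  `S(x) = exp(−½ Σ_j ((z_j(x) − μ_j)/σ_j)²)` with optima anchored at the
  climate of random land cells (so habitat exists) and breadths 0.6 × each
  layer's land SD, jittered ±25%. The *true range* is `{S ≥ τ}`.
* **The range cutoff τ defaults to the species' land-mean suitability.**
  This was a genuinely open design point. With six constraining
  dimensions, a fixed high τ (say 0.5) makes the true range a tiny
  ellipsoid while presence sampling proportional to S scatters most
  records outside it — a world in which even an oracle that thresholds
  *true* suitability cannot recover the range (measured median Jaccard
  0.1–0.5). The land-mean contour is the level set a TSS-optimal
  classifier converges to when presences are drawn ∝ S against a uniform
  background (sensitivity gains balance specificity losses where presence
  density crosses background density), so with this default the recovery
  task is well-posed: the oracle ceiling is ≈ 0.86–0.89, and the full
  pipeline achieves a median Jaccard ≈ 0.8.
* **Occurrences**: `n` draws with replacement ∝ suitability × optional
  effort bias, deduplicated to cells — matching the cleaning contract
  downstream.
* **Land cover**: each analysis cell subdivides into `f²` equal-area
  subcells classed by cutting a smoothed random field at equal quantiles
  (spatial clumping); three class→proportion schemes are perturbations of
  one baseline with the designated urban/garden class always weighted
  highest.
* **Grid**: default 60 × 60 cells of 30′ spanning 30° × 30°. The
  continental *extent* is kept and the resolution coarsened — rather than
  the reverse — because the 200-km exclusion radius is a physical
  distance: on a small 10′ window no cell is ever 200 km from anything.

What a green test does establish: the set logic, cleaning, weighting,
thresholding, permutation, stacking and voting rules behave exactly as
specified, and the full protocol recovers known truth in a world that
satisfies its assumptions. What it does not establish: performance under
real-world violations — sampling bias correlated with climate, niche
truncation at range edges, non-analog future climates, spatial
autocorrelation of residuals, taxonomic noise. The generators make no
attempt to emulate those.

# Numerical choices

* **Half-open cell footprints** `[lon0, lon0+res) × [lat0, lat0+res)`
  with lower-left registration: boundary points belong to exactly one
  cell, so deduplication is deterministic.
* **Spherical Earth, R = 6371 km** for all distances and areas;
  ellipsoidal precision is immaterial at 10′ (and the conventional
  "≈ 220 km² at 50°N" is the spherical value).
* **Max-TSS threshold**: exhaustive scan over midpoints of consecutive
  sorted unique predictions plus {0, 1}, computed by cumulative counts
  (O(n log n)); ties resolve to the lowest optimal threshold. Verified
  against a brute-force 10⁻⁴-grid scan.
* **Evaluation threshold partition**: TSS of a split is computed at the
  threshold optimal on the *evaluation* 20% (the biomod2 convention); the
  protocol source does not say which partition sets it.
* **Hotspot cutoff**: nearest-rank quantile (k-th largest value,
  k = ⌈fraction·N⌉) with ties included, so the flagged share can exceed
  the nominal fraction by the tie mass at the cutoff; with all-distinct
  values exactly k cells are flagged. Deviations > 1 percentage point and
  constant (degenerate) surfaces are logged. An alternative reading —
  "smallest value with ≤ k cells at or above" — can flag *zero* cells
  under heavy ties and contradicts tie inclusion, so it was rejected.
* **Permutation bands**: central intervals from order statistics of the
  null sample, no normal approximation, two verdicts (95%, 99.9%)
  reported side by side.
* **Degenerate inputs**: single-class training sets, empty land masks,
  unmapped land-cover classes, eligible-cell shortfalls and constant
  richness all raise explicit errors or logged degenerate results, never
  silent output.

# Design decisions taken where the protocol is silent

* Prevalence-0.5 weighting is the simplest scheme satisfying "weighted
  presence sum equals weighted absence sum".
* Family ensembles average on the probability scale (literal "weighted
  mean of projections"), with raw-TSS weights (not rescaled).
* The ensemble's own binarization threshold is re-derived on the family's
  pooled calibration data.
* Species losing *all* models of either family are excluded from every
  downstream stage and reported — not zero-filled; the same applies to
  species missing a scenario in the permutation test.
* Hotspot area change is measured in flagged-cell counts by default, with
  a latitude-corrected km² option (`use_area_km2`).
* The consensus risk *value* is the mean of the three scheme values; only
  the flag is protocol-defined.
* BRT and RF are implemented in-package (Rcpp): a weighted CART
  regression-tree primitive under a weighted-bootstrap forest and a
  logistic gradient booster with Newton leaf updates. Hyperparameters sit
  in one config block and are recorded with every fit.
* Raster exchange is CSV (`row,col,value` plus grid metadata in header
  comments); no geospatial stack is required anywhere in the pipeline.

# Known limitations

* No reprojection: everything lives on one geographic lon/lat grid.
* No dispersal, demography, biotic interaction or propagule-pressure
  modelling: "suitable" is climate-only, weighted by land cover.
* The ML-family exclusion buffer requires a calibration extent much
  larger than 200 km; desk-scale runs must trade resolution for extent.
* The synthetic land-cover schemes are stylized; real class-to-proportion
  ratings carry expert judgement the generator only mimics in rank order.
* Future-scenario projections reuse calibration thresholds by design;
  no-analog climate detection (e.g. MESS) is out of scope.
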