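---
title: "Methods: area-based AGB estimation with agbstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: area-based AGB estimation with agbstack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agbstack)
```

## The estimation problem

`agbstack` implements an area-based approach (ABA) to forest aboveground
biomass (AGB) estimation. Field plots provide reference AGB: every tree
with DBH >= 5 cm is converted to dry mass through a species-specific
allometric power law,

$$W = a \cdot D^{b},$$

with $W$ in kg and $D$ the DBH in cm, and plot totals are expressed as a
density in Mg/ha. Remote-sensing features summarize each plot's canopy:
airborne laser scanning (ALS) point clouds yield height, density,
intensity and canopy-cover metrics; a seven-band surface-reflectance
raster yields band combinations, vegetation indices, gray-level
co-occurrence (GLCM) textures and principal components. Regression
models trained on plots are then applied per pixel for wall-to-wall
mapping.

The central methodological questions the package operationalizes are
(i) how to fuse the optical and LiDAR sources — directly, or through
COLI indices built from the best-performing LiDAR variable (BLV) and
each selected optical feature,

$$\mathrm{COLI1}_i = SF_i \times BLV, \qquad
  \mathrm{COLI2}_i = \frac{BLV - SF_i}{BLV + SF_i},$$

and (ii) whether two-layer stacked generalization (SG) over
heterogeneous base regressors improves on the base models themselves.

## Synthetic scenes as the test bed

Reference inventories of this kind are rarely public, so the package
ships a generative scene model (`sceneConfig()`, `buildScene()`) whose
parameters are known exactly; every downstream stage is validated
against that ground truth. A scene consists of:

* **Plots and trees.** 20 m x 30 m plots; stem count per plot
  ~ Poisson(60); species drawn from a fixed mixing vector of eight
  broadleaf-dominated northeastern-China species; DBH from a Weibull
  (shape 2, scale 15 cm) truncated at the 5 cm census threshold. The
  species composition and stand density are *plausible placeholders* —
  the source inventory does not publish them — and are fully
  configurable.
* **True AGB.** Computed from the generated tree lists through the
  packaged allometric table, so the truth table is exactly consistent
  with the allometry module (a conservation test asserts this at 1e-9
  relative).
* **Point clouds.** Return count ~ Poisson(3.6 points/m^2 x area).
  Non-ground heights follow a Beta(2, 1.2) profile scaled to a top
  height $H = h_0\,\mathrm{AGB}^{\gamma}$ with $h_0 = 1.6$,
  $\gamma = 0.5$ (AGB 100 Mg/ha -> 16 m, the right magnitude for these
  forests); 25% of returns are ground hits; intensity decays
  exponentially with canopy depth; ranging noise SD 0.15 m. The Beta
  profile is deliberately simple and monotone: only the rank structure
  of the metrics matters for the tests.
* **Reflectance.** Band $b$ responds to AGB as
  $r_{0b} + r_{1b}\,e^{-\mathrm{AGB}/s_b}$ plus Gaussian noise (SD 0.01),
  clipped to [0, 1]. The exponential makes reflectance insensitive to
  biomass above the band's saturation scale $s_b$ (60-90 Mg/ha,
  matching reported saturation levels for temperate mixed forests); the
  NIR band brightens with biomass ($r_1 < 0$), the visible and SWIR
  bands darken.
* **Terrain.** Flat by default; a configurable planar slope exists only
  to exercise the SCS+C topographic correction.

All randomness flows from one master seed through arithmetic per-plot
substreams, so adding plots never perturbs earlier ones and identical
configurations reproduce byte-identical scenes.

What the generator does *not* emulate: occlusion and multi-return
physics, species-specific crown shapes, spatially correlated stand
structure, atmospheric effects, mixed pixels. Passing tests therefore
demonstrate that the pipeline recovers known structure under the stated
generative model — not that any accuracy level transfers to real
inventories.

## Point-cloud processing conventions

* **Noise removal** (`removeNoise()`): per return, a least-squares plane
  is fitted to the neighbours within a 0.5 m horizontal radius; the
  return is kept iff its plane distance is at most
  $\max(1 \times SD, \varepsilon)$ of the neighbours' residual SD. The
  $\varepsilon$ floor keeps exactly coplanar neighbourhoods; returns
  with fewer than 3 neighbours are kept and counted in a warning.
* **Terrain model** (`interpolateDtmIdw()`): inverse-distance weighting
  at 0.5 m resolution, power 2, 12 nearest ground returns, with an
  exact-hit rule below 1e-9 m. Heights are then normalized by bilinear
  DTM sampling.
* **Metric cutoff**: all height/density/intensity metrics use returns at
  or above 2 m, matching the gap-fraction threshold; the cutoff is an
  argument everywhere.
* **Percentiles**: linear interpolation between closest ranks (R type
  7). The convention of the original processing software is not
  documented, so this common definition is pinned and used consistently
  by both the implementation and the test oracles.
* **Cumulative intensity (AII)**: `int_AII_k` is the intensity share of
  the lowest `ceiling(k% * n)` above-threshold returns ordered *by
  height*; an intensity-ordered variant sits behind `aiiOrder`.
* **LAI**: Beer-Lambert inversion of the gap fraction with extinction
  coefficient 0.5 and nadir scan angle (no angle bookkeeping is
  attempted).
* **Ground labels**: generated clouds are pre-labelled. For unlabeled
  external clouds `classifyGroundSimple()` offers a lowest-point-grid
  fallback; it is explicitly *not* a progressive TIN densification
  filter and is unsuitable for steep terrain.

## Optical conventions

* **SCS+C**: $L_t = L(\cos\theta\cos\alpha + C)/(\cos i + C)$ per band,
  with $C$ estimated as intercept/slope of $L$ on $\cos i$ over all
  unmasked pixels (deterministic, no sampling). On a flat scene the
  factor is exactly 1 and $C$ is irrelevant; the correction preserves
  the band mean there.
* **ND563** is read as a normalized difference — the printed product
  dot is treated as a typeset divide — with the literal product form
  behind `nd563Product = TRUE`.
* **GLCM**: 3 x 3 window, 32 grey levels quantized over the band's
  global range, the four distance-1 offsets pooled symmetrically,
  natural-log entropy with $0\log 0 = 0$, and correlation defined as 0
  for zero-variance windows so constant patches do not poison feature
  tables. None of these knobs are documented upstream; all are
  arguments.
* **Vegetation indices**: the named indices (NDVI, EVI, ARVI, SAVI)
  plus eleven documented companions use the canonical literature
  constants (EVI $G=2.5, C_1=6, C_2=7.5, L=1$; SAVI $L=0.5$). The set
  was chosen to avoid exact linear duplicates of the band-combination
  family, which would make selected feature sets rank-deficient.
* **Plot sampling** defaults to the pixel containing the plot center
  (30 m pixels vs 20 m x 30 m plots means any scheme is approximate
  under geolocation error); an area-weighted mode exists for
  sensitivity runs.

## Feature selection and fusion

Selection is two-step and fully seeded: (1) Pearson correlation with
AGB, keeping features with two-sided $p < 0.05$ from the $t$ transform
of $r$ with $n-2$ df; (2) ten repeated random-forest importance
rankings (1000 trees each at full budget, seeds 0-9), sorted by mean
rank. "Most stable set with high ranking" is not otherwise defined
upstream, so the package pins: mean-rank ascending, ties by $|r|$
descending then name, top 9 per source. The BLV is the selected ALS
feature with the highest univariate OLS $R^2$ (ties to 1e-12 go to
column order, logged). COLI formulas accept negative optical features;
only exact zero denominators yield NaN.

## Models

Eight base algorithms sit behind one `fitModel()`/`predict()` contract.
Stated settings: BP 1000 epochs; RF 1000 trees, seed 10; SVR linear
kernel, cost 1; KNN k = 5, uniform weights; CNN 1000 epochs, batch 30.
Open details were fixed once as package defaults: ELM 64 sigmoid hidden
units with a frozen uniform(-1, 1) hidden layer and a pseudo-inverse
readout (with output intercept, so a 1-unit linear ELM reproduces a
linear map exactly); BP one 32-unit sigmoid hidden layer via `nnet`
(BFGS optimization — the package treats the epoch count as the
iteration cap rather than re-implementing a momentum loop); SVR
epsilon 0.1; the regression tree unconstrained with minimum leaf 1; the
CNN a 1-d convolution (kernel 3, 32 filters, ReLU) over the feature
vector with global average pooling, a dense head, and Adam at 1e-3,
implemented directly in the package and exactly seeded. ELM, BP, SVR,
KNN and CNN standardize features internally (ELM/BP/SVR/CNN also the
targets); MLR and the trees see raw scales.

## Stacking and evaluation

The SG ensemble uses base models RF + SVR + KNN + CNN and one of the
four as meta model. How the meta-training predictions were obtained is
ambiguous in the source description; in-sample stacking is known to
leak, so the default builds the meta-training matrix from seeded
out-of-fold predictions (inner K = 5) and refits the bases on the full
training set for deployment. The in-sample variant remains available as
`inner = "naive"` for comparison. The meta model consumes only the base
predictions, never the original features.

Evaluation is leave-one-out cross-validation with per-fold seeds
derived as master + fold index. Six metrics are reported: $R^2$, RMSE,
rRMSE, MAE, MAPE and PM (residual over total sum of squares). $R^2$ is
the squared Pearson correlation of actual and predicted AGB; the
regression-SS variant $\sum(\hat y - \bar y)^2 / \sum(y - \bar y)^2$ is
emitted as `eq5_r2` because, as printed, it is unbounded for biased
predictions and cannot serve as the headline figure. Negative map
predictions are clipped to 0 — the reported AGB maps of this literature
have a 0 lower bound without a stated rule.

## Budgets and problem sizes

Full-budget settings mirror the stated hyperparameters. Because an
outer LOOCV around an inner K-fold stack multiplies fit counts
($n \times K \times N$ base fits), `budgetProfile("small")` (CNN epochs
100, RF trees 200, inner K 3, BP iterations 200, selection forests 200
trees) is the desk-scale profile used throughout the test suite, and a
`"tiny"` profile serves quick determinism checks, which are
budget-independent. The shipped tests use: a 200-plot scene for signal
recovery, 60-plot scenes over ten seeds for the source-ordering
comparisons, a 30-plot scene for the leakage invariants, and a 24-plot
scene for grid determinism — sizes chosen as the package's own
trade-off between statistical resolution and turnaround.

```{r, eval = FALSE}
sc <- buildScene(sceneConfig(nPlots = 60, seed = 1))
prep <- prepareExperimentFeatures(sc, budget = "small",
                                  normalize = FALSE)
sets <- experimentFeatureSets(prep, c("F1", "F2", "F2+3"))
runExperiments(sets, c("MLR", "RF", "CNN", "SG(RF)"), masterSeed = 1,
               budget = "small")
```

(`normalize = FALSE` is valid on the generator's flat terrain, where
ground elevation is a known constant; with terrain enabled the full
DTM + normalization chain is the route.)

## Numerical choices and degenerate inputs

Zero denominators in ratio features yield NaN rather than errors;
all-NaN metric rows flag non-forest plots with a warning; a degenerate
height span puts all density mass in the first slice; gap fraction 0
reports LAI as NaN; zero-variance features are excluded from selection;
rank-deficient ELM activations take the minimum-norm solution;
rank-deficient PCA returns fewer components with a warning; and every
tie rule (feature ranking, BLV selection) is deterministic and
documented at the function it affects.

## Known limitations

* The synthetic optical scene draws latent pixel AGB independently
  (apart from plot pixels), so map-level spatial structure is not
  realistic; histogram comparisons, not variograms, are the supported
  diagnostic.
* The exact memberships of the upstream 46-elevation/42-intensity
  metric families are not published; the package enumerates a
  documented superset that reproduces every named metric.
* `nnet`'s optimizer is BFGS, not epoch-wise gradient descent; BP
  results are therefore comparable in class but not bitwise to an
  epoch-trained network.
* No uncertainty propagation and no k-fold protocol as the headline
  (k-fold is reachable through the stacking inner machinery but LOOCV
  is the shipped protocol).
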