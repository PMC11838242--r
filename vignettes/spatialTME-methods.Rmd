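---
title: "Quantifying the tumor microenvironment: models and methods in spatialTME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the tumor microenvironment: models and methods in spatialTME}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

spatialTME turns segmented, phenotyped multiplexed-imaging data — per-cell
tables with centroids, a three-level cell-type hierarchy, per-channel mean
intensities and morphology metrics, plus optional channel and label images —
into a catalog of spatial and compositional tumor-microenvironment features,
and then relates that catalog to a binary clinical response label. The
pipeline has a fixed order:

1. **Preprocessing** (optional, for mass-based imaging): linear channel
   compensation and detector-drift normalization.
2. **Compartments**: each field of view (FOV) is split into cancer core,
   cancer border, stroma border and stroma core.
3. **Feature catalog**: densities, density ratios, compositional
   proportions, functional-marker positivity, morphology, abundance and
   neighborhood diversity, nearest cell-cell distances, mixing scores,
   k-means cellular neighborhoods, tile-level ECM clusters, compartment
   areas.
4. **Harmonization**: compartment-redundancy filtering, z-scoring, FOV to
   sample averaging.
5. **Response statistics**: per-feature Welch t-test and median shift,
   rank-aggregated importance scores, paired-timepoint evolution features,
   patient-level label-shuffle robustness.
6. **Response model**: L1-penalized logistic regression with nested
   stratified cross-validation, replicate seeds, consensus top features and
   a 70/30 stratified holdout.

Everything is testable without external data through a synthetic-cohort
generator with known ground truth.

# Preprocessing

## Channel compensation

Contamination in mass-based multiplexed imaging (isotopic spillover,
elemental background, organics, slide background) is modeled linearly. A
coefficient matrix has one row per *source* channel and one column per
*target* channel; entry $(i, j)$ is the fraction of source-$i$ signal
appearing in target $j$. The corrected target is

$$\mathrm{target}' = \max\!\Big(0,\ \mathrm{target} - \sum_i c_{ij}\,
G_\sigma(\mathrm{source}_i)\Big),$$

where $G_\sigma$ is gaussian smoothing with $\sigma = 1$ px. Smoothing turns
integer counts into fractional values so sub-unit coefficients subtract
meaningfully; the value of $\sigma$ is a package choice — any small kernel
serves the purpose. Negatives are clipped to zero because channel data are
counts. Subtraction is linear, so the result is independent of source order.
The coefficients themselves are instrument/panel inputs, not estimated here.

## Detector-drift normalization

Detector sensitivity decays over an acquisition run. The median pulse height
(MPH) of a channel depends only on the detector voltage, not on staining, so
it is a clean per-channel, per-image sensitivity proxy. The procedure:

* a **tuning curve** maps MPH to relative sensitivity in $(0, 1]$. It is
  fitted once, as a cubic polynomial, to a calibration table of
  (MPH, fraction-of-maximum-signal) pairs measured on a standard sample
  across detector settings;
* per run and channel, raw MPH-versus-acquisition-order values are noisy, so
  a quadratic polynomial **drift fit** denoises them (both degrees are
  configurable; low-order polynomials were chosen because drift is slow and
  monotone and the number of FOVs per run is modest);
* each image is divided by its fitted sensitivity. Sensitivity is floored at
  $\varepsilon = 0.05$ so a pathological fit can never amplify an image more
  than 20-fold, and MPH values outside the calibrated range are clamped to
  it rather than extrapolated.

On a simulated run whose true sensitivity decays from 1 to 0.6 the corrected
per-FOV channel means are constant to a coefficient of variation below 0.05
(this is asserted by the test suite).

# Tumor compartments

The cancer region of a FOV is the union of (a) the smoothed, binarized
cancer channel (ECAD by default; gaussian $\sigma = 10$ px; Otsu threshold
unless one is configured) and (b) the pixels of segmented cancer cells.
Holes smaller than 2,500 px² are filled and connected components smaller
than 10,000 px² are dropped — values chosen so that a single ~1.5 mm tumor
core produces 1–3 cancer regions at typical resolutions rather than a
speckle of fragments. Erosion and dilation by the border radius (default
50 px) use the Euclidean distance transform, i.e. an exactly isotropic disc
structuring element; the image edge is treated as mask boundary, so a
full-frame cancer mask still has a border rim:

* cancer core = cancer eroded by $r$;
* cancer border = cancer minus core;
* stroma border = dilation ring;
* stroma core = everything else.

Two cleanup masks are removed from all four compartments *after* the
morphology (order chosen so that dilation can cross thin background gaps
the way a pathologist would draw the margin): slide **background** (pixels
whose smoothed total signal falls below a threshold) and **immune
aggregates** (regions where a gaussian kernel density estimate,
$\sigma = 25$ px, of T/B-cell centroids exceeds a density threshold, kept
when larger than 5,000 px²). The six masks partition the FOV; this is a
class invariant checked on construction.

Cells are assigned to the compartment holding the largest share of their
pixels (or by centroid when label images are absent); exact ties break
deterministically in the order cancer core, cancer border, stroma border,
stroma core. Compartment areas and their six unordered pairwise ratios are
features; a ratio with a zero denominator is recorded as missing with reason
`undefined_ratio`, while a zero numerator is an ordinary 0.

# The feature catalog

All features are computed per FOV; most are computed image-wide and per
compartment. Every value carries metadata (category, compartment, cell
types, markers) and missing values always carry a reason code
(`below_min_cells`, `undefined_ratio`, `zero_area`, `no_cells`,
`no_target`), so downstream consumers can distinguish "not computable" from
"zero".

* **Densities** — count / region area (cells per px²), per broad and
  intermediate type.
* **Density ratios** — $\log_2$ of density pairs: all broad pairs plus
  biologically motivated intermediate pairs (CD8T/CD4T, CD4T/Treg,
  CD8T/Treg, CD68 Mac/CD163 Mac, when present in the hierarchy). A member
  below the minimum density of $5 \times 10^{-7}$ cells/px² is rounded up to
  it; when both members are below, the ratio is not calculated. The log
  scale makes the ratio symmetric around 0 and stable under the later
  z-scoring.
* **Proportions** — for each broad type with at least two intermediate
  children, each child's share of the parent count.
* **Marker positivity** — per intermediate type and functional marker, the
  fraction of cells strictly above the marker threshold (one threshold per
  marker, applied to all cell types). FOVs with fewer than 5 cells of the
  type are missing; a (type, marker) pair is only admitted if the marker is
  positive in at least 5% of that type's cells cohort-wide. Marker
  frequencies are image-wide by default; per-compartment computation exists
  behind an off-by-default flag because compartment counts are often below
  the 5-cell minimum.
* **Morphology** — mean cell size per type; the configured non-redundant
  shape metrics for cancer cells only (shape shifts in other populations
  are too subtle for these summary metrics to capture reliably).
* **Abundance diversity** — Shannon index $H = -\sum_i p_i \ln p_i$
  (natural log) of type proportions, at the broad level and at the
  intermediate level within configured super-groups of broad types (default:
  within every multi-child broad parent).
* **Neighborhood diversity** — per cell, $H$ of the intermediate-type
  composition within a 50 px radius (strict inequality, index cell
  excluded); averaged per index type. Cells with no neighbors are skipped
  rather than counted as zero-diversity.
* **Cell–cell distances** — per ordered pair of distinct broad types, the
  mean over source cells of the distance to the nearest target cell. After
  cohort assembly, pairs whose image-wide values correlate with the target
  type's density beyond $|r| > 0.7$ are dropped: those distances measure
  abundance, not spatial structure.
* **Mixing scores** — per unordered broad pair, the ratio of heterotypic to
  homotypic neighbor links within 50 px. The default pools link counts over
  the FOV before taking the ratio; a per-cell mode (mean of per-cell ratios
  over cells with at least one homotypic neighbor) is provided, because the
  per-cell ratio is undefined at zero homotypic neighbors. The pooled score
  is symmetric in the pair and equals 1 in expectation for a well-mixed
  random labeling of two equally frequent types.
* **Cellular neighborhoods** — cohort-wide k-means (default $k = 12$, 10
  restarts, fixed seed) on per-cell neighbor-composition proportion
  vectors; clusters are relabeled deterministically by their dominant
  centroid loading so ids are stable across runs. Per-FOV neighborhood
  occupancy proportions sum to 1.
* **ECM tiles** — images are cut into 256 px tiles; a pixel is ECM if any
  smoothed ECM channel (collagen, fibronectin, FAP; $\sigma = 2$ px) exceeds
  its threshold. Tiles under 10% ECM area are non-ECM; the rest are
  described by per-marker expression normalized by tile ECM area and
  2-means clustered cohort-wide into Cold (collagen-dominant: the cluster
  with the lower non-collagen centroid) versus Hot collagen. Per-FOV Cold /
  Hot / non-ECM proportions sum to 1.

Spatial primitives are exact, not approximate: neighbor counts, nearest
distances and mixing links agree with an $O(n^2)$ brute-force reference
exactly on random instances (tested up to 500 cells per FOV).

# Harmonization

Fixed order: redundancy filter, then z-score, then FOV-to-sample mean.
Compartment features whose Pearson correlation with their image-wide twin
across FOVs (pairwise-complete) exceeds 0.8 are removed — they duplicate
information; features with fewer than 3 complete pairs are kept with a
warning. Z-scoring uses the sample SD and happens at the FOV level before
averaging a sample's FOVs (a switch moves it after aggregation); zero
variance columns are dropped with a warning. Missing FOVs are simply
omitted from the sample mean. Z-scoring is cohort-wide rather than
per-timepoint by default: cross-timepoint comparisons and evolution
features need values on a common scale.

# Response statistics

Per timepoint and feature, responders and non-responders are compared with
a Welch two-sample t-test (robust to unequal group sizes and variances) and
the difference in medians (responder minus non-responder). P-values are
ranked ascending, absolute median shifts descending, ties receive average
ranks; the two ranks are averaged and rescaled,
$\mathrm{score} = 1 - (\bar{r} - 1)/(N - 1)$, so a feature best on both
criteria scores exactly 1 and one worst on both scores exactly 0. Records
from all timepoints are ranked jointly into a single score set (per-timepoint
ranking is available by flag); no multiple-testing correction is applied
because the score ranks rather than thresholds, though a Benjamini–Hochberg
column is available.

**Evolution features** subtract the earlier from the later timepoint value
per patient for the pairs primary→baseline, baseline→pre-nivo,
baseline→on-nivo and pre-nivo→on-nivo, and feed the same machinery
unchanged.

**Robustness**: outcome labels are shuffled at the patient level (all of a
patient's samples inherit the shuffled label), the whole
univariate-plus-importance analysis is rerun, and the mean p-value and mean
absolute median shift of the top-k features (default 100) are compared with
the observed values across permutations. On a pure-noise cohort the observed
statistic sits inside the permutation distribution; with planted signal it
falls below every permutation.

# Response model

The classifier is L1-penalized logistic regression — the standard
classification form of the lasso — fitted with glmnet. The protocol is
nested and stratified throughout: outer stratified 3-fold CV provides
held-out AUROCs; within each training part an inner stratified 3-fold CV
over a ~50-value log-spaced penalty grid selects the penalty by AUROC; the
whole scheme is replicated over 10 consecutive seeds; the per-seed AUROC is
the mean over outer folds (pooled held-out predictions by flag). Missing
values are mean-imputed and features standardized using training-fold
statistics only — corrupting held-out labels under a fixed split provably
cannot change the fitted model, and the suite asserts this. Consensus **top
features** must be selected (non-zero) in at least 3 replicates and carry an
absolute across-seed mean weight of at least 30% of the largest; they are
reported sorted by absolute mean weight. A 70/30 stratified holdout with
training-only standardization and CV-selected penalty reports AUROC and
AUPRC on the untouched test set.

A practical note on problem sizes: with cohorts of a few dozen patients and
hundreds of features, the nested-CV AUROC of any sparse linear model sits
well below the generative optimum and varies substantially across cohort
realizations; the package's calibration checks therefore pair every
planted-signal cohort with a matched null cohort (where the mean AUROC must
stay near 0.5) rather than relying on a single absolute bar.

# The synthetic cohort generator

The generator emulates the *structure* of a serially sampled multiplexed
imaging study: patients × timepoints × FOVs; a cancer-region geometry (one
or more discs with radii in a configured range) in a stromal surround;
per-intermediate-type Poisson cell counts with region-specific rates
(defaults give a few hundred to a couple of thousand cells per FOV,
matching the realistic per-image range); cells rendered as non-overlapping
discs of radius 4–8 px (dart-throwing placement, larger cells first, with a
hard generation error when a configuration is too dense to place — silent
under-placement would bias density features); marker intensities drawn from
a per-(type, marker) positivity model; and optional channel images (cancer
channel, functional markers, ECM fields) with additive noise.

Patient-level biology enters through latent standard-normal scores named by
the outcome model: `immune_infiltration` scales immune densities by
$e^{0.5 z}$, `mixing` shifts the infiltrate's interleaving on the logit
scale, and `marker_<name>` shifts positivity probabilities on the logit
scale. The **mixing** parameter interpolates between full exclusion of the
infiltrate from the cancer region (0) and a spatially uniform infiltrate
(1); note that even at 0 the tumor–immune mixing score is slightly positive
because cells just inside and just outside the region boundary still touch.
Latents can be restricted to specific timepoints to plant, e.g., an
on-treatment-only effect. The response is drawn from
$\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta^\top z + \beta_0))$ with no
extra label noise; the latents, linear predictor and probabilities are
returned as ground truth.

A second, matrix-level generator skips imaging entirely and produces
sample × feature cohorts with either mean-shift or logistic planted signal;
it is the workhorse for calibrating the statistics and model modules at
known effect sizes.

What the generator deliberately does **not** imitate: real mass-imaging
noise spectra, staining artifacts, irregular tissue morphology, segmentation
errors, or phenotyping mistakes. Passing tests on synthetic cohorts
demonstrate that the estimators compute the intended quantities and recover
planted structure — not that any particular biological effect exists in real
tissue.

# Numerical choices and degenerate inputs

* Distances use strict `< radius`; the index cell is never its own neighbor.
* Shannon indices use the natural log; empty scopes give missing, not 0.
* TIFF IO: label images are 16-bit unsigned (bit-exact round trip); channel
  images are 32-bit float scaled by a fixed 65,535 factor (~1e-7 relative
  precision). Cell tables round-trip through CSV to 1e-12.
* k-means ties and label order are made deterministic by sorting clusters by
  dominant centroid column, then decreasing loading.
* FOVs with zero cells are retained at load (real cohorts contain
  near-empty images) but contribute no cell-based features.
* Problem sizes in the shipped tests (cohorts of 12–60 patients, FOVs of
  256–800 px, 100-permutation and 10-seed protocols) were chosen as the
  smallest sizes at which every calibration check is statistically
  meaningful.

# Known limitations

* Compensation coefficients and marker thresholds are inputs; the package
  neither derives a spillover matrix nor auto-thresholds markers.
* Cell segmentation and phenotyping are upstream: the catalog is only as
  good as the labels it is given.
* The nearest-distance density filter uses a single global cutoff (0.7);
  borderline features near the cutoff are sensitive to cohort composition.
* The mixing-score definition in the literature is ambiguous between pooled
  and per-cell averaging; both are provided, and results should state which
  was used.
* Fiber-object statistics and pixel-level ECM clustering are out of scope;
  ECM is summarized at tile level only.
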