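# spatialTME

Spatial and compositional feature catalogs for multiplexed tissue imaging,
with outcome association and response modeling.

Multiplexed imaging (MIBI, IMC, CODEX and kin) yields, after segmentation
and phenotyping, a table of cells — positions, hierarchical cell-type
labels, per-channel intensities, morphology — plus channel and label images
per field of view (FOV). This package turns that material into a
quantitative description of the tumor microenvironment and relates it to a
binary treatment-response label. It is written for computational biologists
analyzing cohort-scale imaging studies of solid tumors under immunotherapy.

## What it computes

**Tumor compartments.** A cancer mask is built from the smoothed cancer
channel plus cancer-cell segmentations; eroding and dilating it by a border
radius *r* (default 50 px, Euclidean disc) splits each FOV into cancer core,
cancer border, stroma border and stroma core, after removing slide
background and immune aggregates. The six masks partition the image.

**A feature catalog** per FOV, image-wide and per compartment: cell-type
densities and log2 density ratios (with a 5e-7 cells/px² minimum-density
floor), compositional proportions, functional-marker positivity frequencies
(5-cell minimum per image, 5% cohort prevalence admission), morphology,
Shannon diversity of abundances and of 50 px neighborhoods
(H = −Σ p·ln p), mean nearest-other-type distances (filtered when they
merely proxy target density), heterotypic/homotypic mixing scores, k-means
cellular neighborhoods (k = 12), tile-level Cold/Hot-collagen ECM clusters,
and compartment areas with pairwise ratios.

**Harmonization.** Compartment features correlating > 0.8 with their
image-wide twin are dropped; features are z-scored; FOVs are averaged into
(patient, timepoint) samples.

**Response statistics.** Per feature and timepoint: Welch t-test p-value
and responder-minus-non-responder median difference; a rank-aggregated
importance score in [0, 1] (1 − (avg rank − 1)/(N − 1), averaging the
p-value rank and the |median shift| rank); paired-timepoint evolution
features; and patient-level label-shuffle robustness of the top-k features.

**Response model.** L1-penalized logistic regression (glmnet) with nested
stratified 3-fold cross-validation, penalty selected by AUROC, replicated
over 10 seeds; consensus top features (selected in ≥ 3 replicates, |mean
weight| ≥ 30% of the largest); stratified 70/30 holdout with AUROC/AUPRC.

**Synthetic cohorts.** A generator with known ground truth — disc-shaped
cancer regions in stroma, Poisson cell placement, configurable infiltration
and mixing latents, a logistic outcome model — so the full pipeline is
testable end to end without any external data.

Channel preprocessing for mass-based imaging (linear spillover compensation
with smoothed sources; median-pulse-height detector-drift normalization via
a fitted sensitivity curve) is included for workflows that start from raw
channel images.

## Worked example

Simulate a 24-patient cohort in which responders carry a stronger immune
infiltrate, compute the catalog, harmonize, and rank features:

```r
library(spatialTME)

cfg <- simConfig(nPatients = 24, timepoints = "baseline", fovsPerSample = 2,
                 fovSize = 400, cancerRadiusRange = c(90, 130),
                 outcome = list(intercept = 0,
                                coefficients = c(immune_infiltration = 2)),
                 seed = 11)
sim <- simulateCohort(cfg)
sim$cellTable
#> CellTable: 6706 cells, 48 FOVs, 24 patients
#>   markers: 5  morphology: 2

pcfg <- panelConfig(functionalMarkers = names(cfg$markerProbs),
                    thresholds = setNames(rep(1, 5), names(cfg$markerProbs)),
                    cancerMorphology = "elongation",
                    params = list(n_neighborhoods = 8))
cat_ <- computeFeatureCatalog(sim$cellTable, pcfg)
cat_
#> FeatureCatalog: 208 features x 48 FOVs ( 9984 rows, 919 missing )

fm <- buildFeatureMatrix(cat_, sim$fovMeta)
rec <- univariateAssociations(fm, sim$labels, "baseline")
head(importanceScores(rec)[, c("feature_name", "p_value", "importance_score")], 3)
#>                                          feature_name  p_value importance_score
#> density_ratio__broad__Mono_Mac__Stroma::whole_image  3.35e-06            0.988
#> density_ratio__broad__T__Stroma::whole_image         2.46e-05            0.985
#> neighbor_diversity__Fibroblast::whole_image          6.08e-04            0.973

permutationRobustness(fm, sim$labels, k = 50, nPerm = 100, seed = 12)
#> PermutationReport: 100 patient-level label shuffles, top 50 features
#>   observed mean p 0.006997 (shuffles as small: 0.00)
#>   observed mean |med shift| 1.092 (shuffles as large: 0.00)
```

The planted immune-infiltration effect surfaces exactly where it should:
the top-ranked features are immune-versus-stroma density ratios and
diversity measures, their observed top-k mean p-value (0.007) lies below
all 100 label shuffles, and the effect-size statistic behaves the same way.

A command-line front end over the same functions lives in
`inst/scripts/tme-catalog.R` with subcommands `simulate`, `validate`,
`preprocess`, `features`, `harmonize`, `associate` and `model`; run any of
them without arguments to see the options.

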