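smallCfg <- function(...) {
  simConfig(nPatients = 3, timepoints = "baseline", fovsPerSample = 1,
            fovSize = 256, cancerRadiusRange = c(60, 80), seed = 17, ...)
}

test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulateCohort(smallCfg())
  s2 <- simulateCohort(smallCfg())
  expect_identical(cells(s1$cellTable), cells(s2$cellTable))
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$groundTruth, s2$groundTruth)
  c3 <- smallCfg(renderImages = TRUE)
  r1 <- simulateCohort(c3); r2 <- simulateCohort(c3)
  expect_identical(r1$labelImages, r2$labelImages)
  expect_identical(r1$images, r2$images)
})

test_that("cell counts are Poisson-consistent with the configured rates", {
  cfg <- simConfig(nPatients = 6, timepoints = "baseline",
                   fovsPerSample = 2, fovSize = 256,
                   cancerRadiusRange = c(70, 70),
                   outcome = list(intercept = 0, coefficients = c()),
                   seed = 18)
  sim <- simulateCohort(cfg)
  d <- cells(sim$cellTable)
  nFov <- length(unique(d$fov_id))
  cancerArea <- pi * 70^2
  stromaArea <- 256^2 - cancerArea
  dens <- cfg$densities
  im <- unique(cfg$hierarchy@map[, c("intermediate", "broad")])
  immune <- im$intermediate[im$broad %in%
                              c("T", "B", "Mono_Mac", "NK", "Granulocyte")]
  expTotal <- 0
  for (ty in names(dens$stroma)) {
    expTotal <- expTotal + if (ty %in% immune)
      dens$stroma[[ty]] * 256^2 else
      dens$cancer[[ty]] * cancerArea + dens$stroma[[ty]] * stromaArea
  }
  expTotal <- expTotal * nFov
  expect_lt(abs(nrow(d) - expTotal), 3 * sqrt(expTotal))
})

test_that("zero mixing confines the infiltrate outside the tumor", {
  cfg <- smallCfg(mixing = 0)
  sim <- simulateCohort(cfg)
  d <- cells(sim$cellTable)
  # full exclusion: the only tumor-immune contact left is along the region
  # boundary, so the score stays small (but not exactly zero)
  for (f in unique(d$fov_id)) {
    sub <- d[d$fov_id == f, ]
    sc <- mixingScore(sub, sub$cluster_broad, "Cancer", "T", radius = 50)
    if (!is.na(sc)) expect_lt(sc, 0.35)
  }
  # higher mixing raises the cancer/T mixing score
  simHi <- simulateCohort(smallCfg(mixing = 0.6))
  dHi <- cells(simHi$cellTable)
  scLo <- scHi <- numeric()
  for (f in unique(d$fov_id)) {
    s <- d[d$fov_id == f, ]
    scLo <- c(scLo, mixingScore(s, s$cluster_broad, "Cancer", "T", 50))
  }
  for (f in unique(dHi$fov_id)) {
    s <- dHi[dHi$fov_id == f, ]
    scHi <- c(scHi, mixingScore(s, s$cluster_broad, "Cancer", "T", 50))
  }
  expect_gt(mean(scHi, na.rm = TRUE), 2 * mean(scLo, na.rm = TRUE))
})

test_that("rendered artifacts pass core validation with zero violations", {
  sim <- simulateCohort(smallCfg(renderImages = TRUE))
  ct <- sim$cellTable
  expect_true(validObject(ct))
  for (f in fovIds(ct)) {
    viol <- validateFov(fovCells(ct, f), sim$labelImages[[f]])
    expect_length(viol, 0)
  }
  imgs <- sim$images[[fovIds(ct)[1]]]
  expect_true(all(c("ECAD", "Collagen1", "Fibronectin", "FAP") %in%
                    names(imgs)))
  expect_true(all(vapply(imgs, function(m) all(m >= 0), TRUE)))
})

test_that("a null outcome model hits the intercept-implied response rate", {
  cfg <- simConfig(nPatients = 500, timepoints = "baseline",
                   fovsPerSample = 1, fovSize = 96,
                   cancerRadiusRange = c(25, 30),
                   densities = local({
                     d <- spatialTME:::.defaultDensities()
                     d$cancer <- d$cancer * 0.5
                     d$stroma <- d$stroma * 0.5
                     d
                   }),
                   outcome = list(intercept = qlogis(0.35),
                                  coefficients = c()),
                   seed = 19)
  sim <- simulateCohort(cfg)
  frac <- mean(sim$labels$response)
  expect_lt(abs(frac - 0.35), 3 * sqrt(0.35 * 0.65 / 500))
})

test_that("a planted infiltration effect surfaces in the importance ranks", {
  cfg <- simConfig(nPatients = 24, timepoints = "baseline",
                   fovsPerSample = 2, fovSize = 400,
                   cancerRadiusRange = c(90, 130),
                   outcome = list(intercept = 0,
                                  coefficients = c(immune_infiltration = 2)),
                   seed = 20)
  sim <- simulateCohort(cfg)
  pcfg <- panelConfig(functionalMarkers = names(cfg$markerProbs),
                      thresholds = setNames(rep(1, 5),
                                            names(cfg$markerProbs)),
                      cancerMorphology = "elongation",
                      params = list(n_neighborhoods = 6))
  cat_ <- computeFeatureCatalog(sim$cellTable, pcfg)
  fm <- suppressWarnings(buildFeatureMatrix(cat_, sim$fovMeta))
  rec <- univariateAssociations(fm, sim$labels, "baseline")
  sc <- importanceScores(rec)
  top5 <- head(sc$feature_name, 5)
  immuneHit <- grepl("density.*(T|B|Mac|NK|CD8|CD4|Treg|Bcell|Mono|Neutrophil)",
                     top5) | grepl("ratio", top5)
  expect_true(any(immuneHit))
})

test_that("an on-treatment-only effect lands in on-nivo and evolution", {
  cfg <- simConfig(nPatients = 24, timepoints = c("baseline", "on_nivo"),
                   fovsPerSample = 1, fovSize = 320,
                   cancerRadiusRange = c(80, 110),
                   outcome = list(intercept = 0,
                                  coefficients = c(immune_infiltration = 2.5)),
                   latentTimepoints = list(immune_infiltration = "on_nivo"),
                   seed = 21)
  sim <- simulateCohort(cfg)
  pcfg <- panelConfig(params = list(n_neighborhoods = 4))
  cat_ <- computeFeatureCatalog(sim$cellTable, pcfg)
  fm <- suppressWarnings(buildFeatureMatrix(cat_, sim$fovMeta))
  recB <- univariateAssociations(fm, sim$labels, "baseline")
  recO <- univariateAssociations(fm, sim$labels, "on_nivo")
  ev <- evolutionFeatures(fm, pairs = list(c("baseline", "on_nivo")))
  recE <- univariateAssociations(ev, sim$labels, "baseline__to__on_nivo")
  sc <- importanceScores(rbind(recB, recO, recE))
  top <- head(sc, 20)
  expect_gt(sum(top$timepoint != "baseline"), 10)
  # baseline p-values behave like a null (no strong enrichment of tiny p)
  expect_gt(min(recB$p_value) * nrow(recB), 1e-3)
})

test_that("overcrowded configurations fail with a generation error", {
  dens <- spatialTME:::.defaultDensities()
  dens$cancer <- dens$cancer * 60
  cfg <- simConfig(nPatients = 1, timepoints = "baseline",
                   fovsPerSample = 1, fovSize = 128,
                   cancerRadiusRange = c(50, 60), densities = dens,
                   seed = 22)
  expect_error(simulateCohort(cfg), "generation error")
})
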