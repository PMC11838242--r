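regionsOf <- function(cells, area) list(whole_image = list(cells = cells,
                                                           area = area))

test_that("densities are count over area with Poisson-consistent estimates", {
  cells <- patternCells(runif(10, 0, 999), runif(10, 0, 999), "X")
  r <- regionsOf(cells, 1e6)
  d <- cellDensities(r, "f1", "broad", c("X", "Y"))
  expect_equal(d$value[d$cell_types == "X"], 1e-5)
  expect_equal(d$value[d$cell_types == "Y"], 0)

  # homogeneous Poisson with intensity 2e-5 over 1e6 px^2
  set.seed(21)
  lambda <- 2e-5; A <- 1e6
  n <- rpois(1, lambda * A)
  pp <- patternCells(runif(n, 0, 1000), runif(n, 0, 1000), "X")
  est <- cellDensities(regionsOf(pp, A), "f1", "broad", "X")$value
  expect_lt(abs(est - lambda), 3 * sqrt(lambda / A))

  # zero-area region -> missing with reason
  z <- cellDensities(regionsOf(cells, 0), "f1", "broad", "X")
  expect_true(is.na(z$value))
  expect_equal(z$reason, "zero_area")
})

test_that("density ratios apply the minimum-density floor rules", {
  mk <- function(a, b) {
    dens <- data.frame(fov_id = "f1",
      feature_name = paste0("density__broad__", c("A", "B")),
      compartment = "whole_image", value = c(a, b), category = "density",
      cell_types = c("A", "B"), markers = "", reason = NA_character_)
    densityRatioFeatures(dens, "f1", "broad", list(c("A", "B")))
  }
  expect_equal(mk(1e-5, 1e-5)$value, 0)
  expect_equal(mk(1e-5, 1e-8)$value, log2(20), tolerance = 1e-12)
  both <- mk(1e-8, 2e-8)
  expect_true(is.na(both$value))
  expect_equal(both$reason, "undefined_ratio")
})

test_that("proportions cover multi-child parents and sum to one", {
  h <- tinyHierarchy()
  cells <- patternCells(1:10 * 10, rep(5, 10),
                        c(rep("CD8T", 4), rep("CD4T", 3), rep("Treg", 3)))
  cells$cluster_broad <- "T"
  p <- proportionFeatures(regionsOf(cells, 1e4), "f1", h)
  cd8 <- p$value[p$feature_name == "proportion__CD8T__of__T"]
  expect_equal(cd8, 0.4)
  tkids <- p[grepl("__of__T$", p$feature_name), ]
  expect_equal(sum(tkids$value), 1)
  # single-child parents emit nothing
  expect_false(any(grepl("__of__B$", p$feature_name)))
  expect_false(any(grepl("__of__Mono_Mac$", p$feature_name)))
})

test_that("marker frequencies honor threshold, minimum cells and admission", {
  cells <- patternCells(1:20 * 10, rep(5, 20), rep("Mac", 20))
  cells$cluster_intermediate <- "Mac"
  cells$PDL1 <- c(rep(2, 8), rep(0.1, 12))
  mf <- markerFrequencyFeatures(regionsOf(cells, 1e4), "f1", "Mac",
                                c(PDL1 = 1))
  expect_equal(mf$value, 0.40)

  few <- cells[1:4, ]
  mf2 <- markerFrequencyFeatures(regionsOf(few, 1e4), "f1", "Mac",
                                 c(PDL1 = 1))
  expect_true(is.na(mf2$value))
  expect_equal(mf2$reason, "below_min_cells")

  # cohort-wide 5% admission: a 2%-prevalent marker is dropped
  h <- tinyHierarchy()
  big <- patternCells(seq_len(100), rep(1, 100), rep("Mac", 100))
  big$cluster_detailed <- "Mac_x"; big$cluster_broad <- "Mono_Mac"
  big$PDL1 <- c(rep(2, 2), rep(0.1, 98))
  ct <- cellTable(big, h, markers = "PDL1",
                  fovInfo = data.frame(fov_id = "f1", width = 200,
                                       height = 200))
  cat_ <- catalogFrom(data.frame(fov_id = "f1",
    feature_name = "marker_pos__Mac__PDL1", compartment = "whole_image",
    value = 0.02, category = "marker_positivity", cell_types = "Mac",
    markers = "PDL1", reason = NA_character_))
  kept <- filterMarkerPrevalence(cat_, ct, floor = 0.05,
                                 thresholds = c(PDL1 = 1))
  expect_equal(nrow(featureValues(kept)), 0)
  kept2 <- filterMarkerPrevalence(cat_, ct, floor = 0.01,
                                  thresholds = c(PDL1 = 1))
  expect_equal(nrow(featureValues(kept2)), 1)
})

test_that("morphology reports size for all types, shape for cancer only", {
  cfg <- panelConfig(cancerMorphology = "elongation")
  cells <- patternCells(c(10, 20, 30), c(5, 5, 5), c("Tumor", "Tumor", "Mac"))
  cells$cluster_broad <- c("Cancer", "Cancer", "Mono_Mac")
  cells$cell_area <- c(100, 300, 80)
  cells$elongation <- c(1.5, 2.5, 9)
  m <- morphologyFeatures(cells, "f1", c("Tumor", "Mac", "Fibro"), cfg)
  expect_equal(m$value[m$feature_name == "size__Tumor"], 200)
  expect_equal(m$value[m$feature_name == "size__Mac"], 80)
  expect_true(is.na(m$value[m$feature_name == "size__Fibro"]))
  expect_equal(m$value[m$feature_name == "morph__elongation__cancer"], 2)
  expect_false(any(grepl("morph__elongation__Mac", m$feature_name)))
})

test_that("Shannon index matches the closed form", {
  expect_equal(shannonIndex(c(5, 0, 0)), 0)
  expect_equal(shannonIndex(rep(3, 4)), log(4), tolerance = 1e-15)
  expect_equal(shannonIndex(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 0.5 * log(0.25)), tolerance = 1e-15)
  expect_true(is.na(shannonIndex(numeric())))
  # H in [0, log K], maximum iff uniform
  set.seed(22)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    p <- runif(k)
    expect_lte(shannonIndex(p), log(k) + 1e-12)
    expect_gte(shannonIndex(p), 0)
  }
})

test_that("neighbor diversity averages per-cell entropy by index type", {
  # every cell surrounded only by its own type -> 0
  cells <- patternCells(c(0, 10, 200, 210), c(0, 0, 0, 0),
                        c("A", "A", "B", "B"))
  cells$cluster_intermediate <- cells$cluster_broad
  cnt <- neighborCounts(cells, cells$cluster_intermediate, radius = 50,
                        levels = c("A", "B"))
  nd <- neighborDiversityFeatures(cells, cnt, "f1", c("A", "B"))
  expect_equal(nd$value, c(0, 0))

  # equal counts of three neighbor types -> log 3
  g <- patternCells(c(0, 10, 0, 10), c(0, 0, 10, 10),
                    c("IDX", "N1", "N2", "N3"))
  g$cluster_intermediate <- g$cluster_broad
  cnt2 <- neighborCounts(g, g$cluster_intermediate, radius = 50,
                         levels = c("IDX", "N1", "N2", "N3"))
  nd2 <- neighborDiversityFeatures(g, cnt2, "f1", "IDX")
  expect_equal(nd2$value, log(3), tolerance = 1e-12)
})

test_that("dense random labeling drives mean neighbor diversity to ln K", {
  set.seed(23)
  n <- 500; K <- 4
  cells <- patternCells(runif(n, 0, 200), runif(n, 0, 200),
                        sample(paste0("T", 1:K), n, replace = TRUE))
  cells$cluster_intermediate <- cells$cluster_broad
  cnt <- neighborCounts(cells, cells$cluster_intermediate, radius = 50,
                        levels = paste0("T", 1:K))
  nd <- neighborDiversityFeatures(cells, cnt, "f1", paste0("T", 1:K))
  expect_equal(mean(nd$value), log(K), tolerance = 0.03)
})

test_that("planted neighborhood archetypes are recovered by k-means", {
  set.seed(24)
  K <- 3; perArch <- 300
  arch <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8))
  counts <- do.call(rbind, lapply(1:K, function(k)
    t(rmultinom(perArch, 20, arch[k, ]))))
  colnames(counts) <- c("A", "B", "C")
  cellsAll <- patternCells(runif(K * perArch), runif(K * perArch), "A")
  cellsAll$fov_id <- rep(c("f1", "f2"), length.out = K * perArch)
  truth <- rep(1:K, each = perArch)
  nb <- cellNeighborhoodFeatures(cellsAll, counts, k = 3, seed = 1)
  # adjusted Rand index vs the planted archetypes
  ari <- mclust::adjustedRandIndex(truth, nb$assignment)
  expect_gt(ari, 0.9)
  # per-FOV proportions sum to one
  f1 <- nb$features[nb$features$fov_id == "f1", ]
  expect_equal(sum(f1$value), 1)

  # identical vectors, k = 1 -> one cluster holding everything
  same <- matrix(5L, 40, 2, dimnames = list(NULL, c("A", "B")))
  cells1 <- patternCells(runif(40), runif(40), "A")
  nb1 <- cellNeighborhoodFeatures(cells1, same, k = 1, seed = 1)
  expect_equal(unique(nb1$assignment), 1L)
  expect_equal(nb1$features$value[1], 1)

  expect_error(cellNeighborhoodFeatures(cells1, same, k = 99, seed = 1),
               "clustering error")
})

test_that("neighborhood relabeling is deterministic across runs", {
  set.seed(25)
  counts <- t(rmultinom(200, 15, c(0.3, 0.4, 0.3)))
  colnames(counts) <- c("A", "B", "C")
  cells <- patternCells(runif(200), runif(200), "A")
  n1 <- cellNeighborhoodFeatures(cells, counts, k = 4, seed = 9)
  n2 <- cellNeighborhoodFeatures(cells, counts, k = 4, seed = 9)
  expect_identical(n1$assignment, n2$assignment)
  expect_identical(n1$centers, n2$centers)
})

test_that("ECM tiles are masked, clustered and reported as proportions", {
  cfg <- panelConfig(ecmThresholds = c(Collagen1 = 0.5, Fibronectin = 0.5,
                                       FAP = 0.5),
                     params = list(tile_size = 64, ecm_smooth_sigma = 1,
                                   kmeans_seed = 3))
  blank <- list(Collagen1 = matrix(0, 128, 128),
                Fibronectin = matrix(0, 128, 128),
                FAP = matrix(0, 128, 128))
  f0 <- ecmTileFeatures(list(fovA = blank), cfg)
  expect_equal(f0$value[grepl("non_ecm", f0$feature_name)], 1)
  expect_equal(sum(f0$value), 1)

  # collagen-only half vs collagen+FAP half -> opposite clusters
  col <- matrix(1.5, 128, 128)
  fap <- matrix(0, 128, 128); fap[, 65:128] <- 1.2
  imgs <- list(Collagen1 = col, Fibronectin = matrix(0, 128, 128), FAP = fap)
  f1 <- ecmTileFeatures(list(fovB = imgs), cfg)
  cold <- f1$value[grepl("cold", f1$feature_name)]
  hot <- f1$value[grepl("hot", f1$feature_name)]
  expect_equal(cold, 0.5)
  expect_equal(hot, 0.5)
  expect_equal(sum(f1$value), 1)
  expect_error(ecmTileFeatures(list(f = imgs[1:2]), cfg), "config error")
})
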