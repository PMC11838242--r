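discAt <- function(h, w, cx, cy, r) spatialTME:::discMask(h, w, cx, cy, r)

test_that("disc geometry matches the closed-form annulus areas", {
  cm <- discAt(750, 750, 374, 374, 300)
  ms <- deriveCompartments(cm, radius = 50, fovId = "f1")
  a <- compartmentAreas(ms)
  expect_equal(a[["cancer_core"]], pi * 250^2, tolerance = 0.02)
  expect_equal(a[["cancer_border"]], pi * (300^2 - 250^2), tolerance = 0.02)
  expect_equal(a[["stroma_border"]], pi * (350^2 - 300^2), tolerance = 0.02)
  # area features reproduce the same geometric ratio
  feats <- compartmentAreaFeatures(ms)
  ratio <- feats$value[feats$feature_name ==
                         "area_ratio__cancer_core__cancer_border"]
  expect_equal(ratio, 250^2 / (300^2 - 250^2), tolerance = 0.02)
})

test_that("degenerate cancer masks produce the forced compartments", {
  empty <- matrix(FALSE, 200, 200)
  ms <- deriveCompartments(empty, radius = 50)
  a <- compartmentAreas(ms)
  expect_equal(a[["stroma_core"]], 200 * 200)
  expect_equal(sum(a[c("cancer_core", "cancer_border", "stroma_border")]), 0)
  feats <- compartmentAreaFeatures(ms)
  # 0/0 ratio omitted with a reason; 0/positive is a plain zero
  cb <- feats[feats$feature_name == "area_ratio__cancer_core__cancer_border", ]
  expect_true(is.na(cb$value))
  expect_equal(cb$reason, "undefined_ratio")
  expect_equal(feats$value[feats$feature_name ==
    "area_ratio__cancer_core__stroma_core"], 0)

  full <- matrix(TRUE, 200, 200)
  ms2 <- deriveCompartments(full, radius = 50)
  a2 <- compartmentAreas(ms2)
  expect_equal(a2[["stroma_border"]], 0)
  expect_equal(a2[["stroma_core"]], 0)
  # the border is the 50-px inner rim
  expect_equal(a2[["cancer_border"]], 200^2 - 100^2, tolerance = 0.05)
})

test_that("equal-area compartments give unit ratios", {
  ms <- rectMaskSet()
  feats <- compartmentAreaFeatures(ms)
  ratios <- feats$value[grepl("area_ratio", feats$feature_name)]
  expect_equal(ratios, rep(1, 6))
})

test_that("cancer mask is built from channel plus cells with size rules", {
  cfg <- panelConfig(params = list(min_component = 2000, hole_fill = 500,
                                   smooth_sigma = 3))
  lab <- matrix(0L, 300, 300)
  cells <- patternCells(numeric(), numeric(), character())
  cells$cluster_broad <- character()
  # zero signal, zero cancer cells -> empty mask
  m0 <- buildCancerMask(matrix(0, 300, 300), cells, lab, cfg)
  expect_false(any(m0))

  # a solid disc of cancer-cell pixels, radius 60 -> area within 5%
  ids <- 1L
  lab2 <- matrix(0L, 300, 300)
  lab2[discAt(300, 300, 150, 150, 60)] <- 1L
  cells2 <- patternCells(150, 150, "Cancer")
  m1 <- buildCancerMask(NULL, cells2, lab2, cfg)
  expect_equal(sum(m1), pi * 60^2, tolerance = 0.05)
  expect_equal(max(EBImage::bwlabel(m1)), 1)

  # two islands straddling the component cutoff: only the large one stays
  lab3 <- matrix(0L, 300, 300)
  lab3[discAt(300, 300, 80, 80, 40)] <- 1L    # ~5000 px^2 (kept)
  lab3[discAt(300, 300, 230, 230, 20)] <- 2L  # ~1250 px^2 (dropped)
  cells3 <- patternCells(c(80, 230), c(80, 230), c("Cancer", "Cancer"))
  m2 <- buildCancerMask(NULL, cells3, lab3, cfg)
  expect_equal(max(EBImage::bwlabel(m2)), 1)
  expect_true(m2[81, 81])
  expect_false(m2[231, 231])
})

test_that("cells are assigned by maximum overlap with deterministic ties", {
  ms <- rectMaskSet()  # 40x40, compartments are 10-px vertical bands
  lab <- matrix(0L, 40, 40)
  lab[15:18, 3:6] <- 1L     # fully inside cancer_core (cols 1-10)
  lab[15:18, 17:26] <- 2L   # 40% cancer_border (17:20), 60% stroma_border
  lab[15:18, 26:35] <- 3L   # 50/50 stroma_border (26:30) / stroma_core
  cells <- patternCells(c(4, 21, 30), c(16, 16, 16), rep("T", 3))
  got <- assignCells(cells, lab, ms)
  expect_equal(got, c("cancer_core", "stroma_border", "stroma_border"))
})

test_that("random geometries always partition the image", {
  set.seed(11)
  for (i in 1:100) {
    sz <- 128
    n <- sample(1:3, 1)
    cm <- matrix(FALSE, sz, sz)
    for (k in seq_len(n))
      cm <- cm | discAt(sz, sz, runif(1, 0, sz), runif(1, 0, sz),
                        runif(1, 10, 50))
    bg <- discAt(sz, sz, runif(1, 0, sz), runif(1, 0, sz), runif(1, 5, 25))
    ag <- discAt(sz, sz, runif(1, 0, sz), runif(1, 0, sz), runif(1, 5, 20))
    ms <- deriveCompartments(cm, background = bg, aggregates = ag,
                             radius = sample(10:40, 1))
    expect_true(validObject(ms))  # validity asserts the partition
  }
})

test_that("growing the border radius never grows the cancer core", {
  cm <- discAt(300, 300, 150, 150, 100)
  areas <- sapply(c(10, 25, 40, 60), function(r)
    compartmentAreas(deriveCompartments(cm, radius = r))[["cancer_core"]])
  expect_true(all(diff(areas) <= 0))
})

test_that("background and aggregates are excluded from compartments", {
  cm <- discAt(200, 200, 100, 100, 60)
  bg <- matrix(FALSE, 200, 200); bg[, 1:20] <- TRUE
  cells <- patternCells(rep(c(100, 104, 108), 4),
                        rep(c(100, 104, 108, 112), each = 3), rep("T", 12))
  cfg <- panelConfig(params = list(aggregate_density = 1e-4,
                                   aggregate_min_area = 100))
  ag <- immuneAggregateMask(cells, c(200, 200), cfg)
  expect_true(any(ag))
  ms <- deriveCompartments(cm, background = bg, aggregates = ag, radius = 30)
  for (cp in COMPARTMENTS) {
    expect_false(any(ms@masks[[cp]] & bg))
    expect_false(any(ms@masks[[cp]] & ms@aggregates))
  }
})
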