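fmFrom <- function(x, timepoint = "baseline") {
  pats <- sprintf("P%02d", seq_len(nrow(x)))
  rownames(x) <- paste(pats, timepoint, sep = "||")
  new("FeatureMatrix", values = x,
      sampleInfo = data.frame(patient_id = pats, timepoint = timepoint),
      featureInfo = data.frame(column = colnames(x),
        feature_name = sub("::.*$", "", colnames(x)),
        compartment = "whole_image", category = NA_character_,
        cell_types = "", markers = ""))
}

test_that("univariate associations report Welch p and median difference", {
  # identical class distributions -> p = 1, med_diff = 0
  x <- matrix(c(1, 2, 3, 4, 1, 2, 3, 4), ncol = 1,
              dimnames = list(NULL, "f::whole_image"))
  fm <- fmFrom(x)
  lab <- data.frame(patient_id = sprintf("P%02d", 1:8),
                    response = rep(c(1, 0), each = 4))
  rec <- univariateAssociations(fm, lab, "baseline")
  expect_equal(rec$p_value, 1)
  expect_equal(rec$med_diff, 0)

  # med_diff is antisymmetric under label inversion
  set.seed(41)
  x2 <- matrix(rnorm(40), ncol = 2,
               dimnames = list(NULL, c("a::whole_image", "b::whole_image")))
  fm2 <- fmFrom(x2)
  lab2 <- data.frame(patient_id = sprintf("P%02d", 1:20),
                     response = rep(c(1, 0), 10))
  r1 <- univariateAssociations(fm2, lab2, "baseline")
  lab3 <- lab2; lab3$response <- 1 - lab3$response
  r2 <- univariateAssociations(fm2, lab3, "baseline")
  expect_equal(r1$med_diff, -r2$med_diff)
  expect_equal(r1$p_value, r2$p_value)

  # single-class cohorts are an analysis error
  lab4 <- lab2; lab4$response <- 1
  expect_error(univariateAssociations(fm2, lab4, "baseline"), "single")
})

test_that("a 2-SD mean shift is detected with high power", {
  set.seed(42)
  hits <- replicate(100, {
    x <- matrix(c(rnorm(20, 2), rnorm(20, 0)), ncol = 1,
                dimnames = list(NULL, "f::whole_image"))
    fm <- fmFrom(x)
    lab <- data.frame(patient_id = sprintf("P%02d", 1:40),
                      response = rep(c(1, 0), each = 20))
    univariateAssociations(fm, lab, "baseline")$p_value < 1e-4
  })
  expect_gte(mean(hits), 0.95)
})

# independent ranking oracle: ranks by explicit pairwise comparison with
# average ties, scores by the definitional rescaling
oracleImportance <- function(p, med) {
  rankOf <- function(v) {
    sapply(seq_along(v), function(i)
      sum(v < v[i]) + (1 + sum(v == v[i])) / 2)
  }
  pr <- rankOf(p)
  er <- rankOf(-abs(med))
  avg <- (pr + er) / 2
  1 - (avg - 1) / (length(p) - 1)
}

test_that("importance scores match the exhaustive oracle on small tables", {
  set.seed(43)
  for (n in 2:8) {
    for (rep in 1:5) {
      p <- round(runif(n), 2)            # rounding forces occasional ties
      med <- round(rnorm(n), 1)
      rec <- data.frame(feature_name = paste0("f", 1:n),
                        timepoint = "baseline", p_value = p, med_diff = med)
      got <- importanceScores(rec)
      want <- oracleImportance(p, med)
      expect_equal(got$importance_score[match(rec$feature_name,
                                              got$feature_name)], want)
    }
  }
})

test_that("importance extremes and order invariance hold", {
  rec <- data.frame(feature_name = c("best", "mid", "worst"),
                    timepoint = "baseline",
                    p_value = c(0.001, 0.5, 0.9),
                    med_diff = c(3, 1, 0.1))
  sc <- importanceScores(rec)
  expect_equal(sc$importance_score[sc$feature_name == "best"], 1)
  expect_equal(sc$importance_score[sc$feature_name == "worst"], 0)

  perm <- importanceScores(rec[c(3, 1, 2), ])
  expect_equal(perm[order(perm$feature_name), "importance_score"],
               sc[order(sc$feature_name), "importance_score"])
})

test_that("joint and per-timepoint ranking modes differ as documented", {
  rec <- rbind(
    data.frame(feature_name = "f1", timepoint = "baseline",
               p_value = 0.001, med_diff = 2),
    data.frame(feature_name = "f1", timepoint = "on_nivo",
               p_value = 0.5, med_diff = 0.2),
    data.frame(feature_name = "f2", timepoint = "baseline",
               p_value = 0.9, med_diff = 0.1))
  joint <- importanceScores(rec)
  expect_equal(nrow(joint), 3)        # feature x timepoint records pooled
  per <- importanceScores(rec, perTimepoint = TRUE)
  expect_equal(per$importance_score[per$timepoint == "on_nivo"], 1)
})

test_that("evolution features are later-minus-earlier and compose", {
  x <- matrix(c(1, 2, 1.0, 2.5), ncol = 1,
              dimnames = list(NULL, "f::whole_image"))
  si <- data.frame(patient_id = c("P1", "P2", "P1", "P2"),
                   timepoint = c("baseline", "baseline",
                                 "on_nivo", "on_nivo"))
  rownames(x) <- paste(si$patient_id, si$timepoint, sep = "||")
  fm <- new("FeatureMatrix", values = x, sampleInfo = si,
            featureInfo = data.frame(column = "f::whole_image",
              feature_name = "f", compartment = "whole_image",
              category = NA_character_, cell_types = "", markers = ""))
  ev <- evolutionFeatures(fm, pairs = list(c("baseline", "on_nivo")))
  v <- matrixValues(ev)
  expect_equal(v["P1||baseline__to__on_nivo", 1], 0)
  expect_equal(v["P2||baseline__to__on_nivo", 1], 0.5)
  lab <- data.frame(patient_id = c("P1", "P2"), response = c(1, 0))
  expect_error(univariateAssociations(ev, lab, "baseline__to__on_nivo"),
               NA)
})

test_that("shuffled labels yield near-uniform p-values on pure noise", {
  sc <- simulateFeatureCohort(40, 300, nPlanted = 0, seed = 44)
  lab <- sc$labels
  set.seed(45)
  lab$response <- sample(lab$response)
  rec <- univariateAssociations(sc$fm, lab, "baseline")
  ks <- suppressWarnings(ks.test(rec$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation robustness is deterministic and calibrated", {
  sc <- simulateFeatureCohort(30, 60, nPlanted = 20, effect = 1.5,
                              model = "shift", seed = 46)
  r1 <- permutationRobustness(sc$fm, sc$labels, k = 20, nPerm = 15, seed = 9)
  r2 <- permutationRobustness(sc$fm, sc$labels, k = 20, nPerm = 15, seed = 9)
  expect_identical(r1, r2)
  expect_gte(r1$exceed_p, 0); expect_lte(r1$exceed_p, 1)
  # planted signal: observed top-k mean p below every shuffle
  expect_true(all(r1$perm_mean_p > r1$observed[["mean_p"]]))
})
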