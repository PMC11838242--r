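# Shared fixtures, built in code at test time.

tinyHierarchy <- function() {
  clusterHierarchy(data.frame(
    detailed = c("Tumor_a", "Tumor_b", "CD8T_x", "CD4T_x", "Treg_x",
                 "Bcell_x", "Mac_x", "Fibro_x"),
    intermediate = c("Tumor", "Tumor", "CD8T", "CD4T", "Treg",
                     "Bcell", "Mac", "Fibro"),
    broad = c("Cancer", "Cancer", "T", "T", "T", "B", "Mono_Mac", "Stroma")))
}

# minimal well-formed per-cell data.frame
tinyCells <- function(n = 3, fov = "f1", detailed = "CD8T_x") {
  data.frame(
    patient_id = "P1", timepoint = "baseline", fov_id = fov,
    cell_id = seq_len(n),
    centroid_x = seq(10, by = 20, length.out = n),
    centroid_y = seq(10, by = 20, length.out = n),
    cell_area = rep(100, n),
    cluster_detailed = rep_len(detailed, n),
    stringsAsFactors = FALSE)
}

# point-pattern cells for spatial tests: explicit coordinates and types
patternCells <- function(x, y, type) {
  n <- length(x)
  data.frame(patient_id = rep("P1", n), timepoint = rep("baseline", n),
             fov_id = rep("f1", n), cell_id = seq_len(n),
             centroid_x = x, centroid_y = y, cell_area = rep(50, n),
             cluster_detailed = rep(NA_character_, n),
             cluster_intermediate = type,
             cluster_broad = type, stringsAsFactors = FALSE)
}

# brute-force neighbor counts via stats::dist (independent of the package's
# block-wise computation)
bruteNeighborCounts <- function(cells, types, radius, levels) {
  d <- as.matrix(dist(cbind(cells$centroid_x, cells$centroid_y)))
  diag(d) <- Inf
  out <- matrix(0L, nrow(cells), length(levels),
                dimnames = list(NULL, levels))
  for (i in seq_len(nrow(cells)))
    for (k in seq_along(levels))
      out[i, k] <- sum(d[i, ] < radius & types == levels[k])
  out
}

# a partition-valid CompartmentMaskSet with rectangular compartments
rectMaskSet <- function(h = 40, w = 40, fov = "f1") {
  f <- function() matrix(FALSE, h, w)
  m <- list(cancer_core = f(), cancer_border = f(), stroma_border = f(),
            stroma_core = f())
  m$cancer_core[, 1:10] <- TRUE
  m$cancer_border[, 11:20] <- TRUE
  m$stroma_border[, 21:30] <- TRUE
  m$stroma_core[, 31:40] <- TRUE
  new("CompartmentMaskSet", fovId = fov, masks = m,
      background = f(), aggregates = f())
}

# build a FeatureCatalog directly from a long data.frame sketch
catalogFrom <- function(df) {
  need <- c("fov_id", "feature_name", "compartment", "value", "category",
            "cell_types", "markers", "reason")
  for (nm in setdiff(need, names(df)))
    df[[nm]] <- if (nm == "value") NA_real_ else
      if (nm == "reason") NA_character_ else ""
  if (!"category" %in% names(df) || all(df$category == ""))
    df$category <- "density"
  new("FeatureCatalog", values = df[, need])
}

# vectors with an exact target Pearson correlation to x
correlatedVector <- function(x, r, seed = 1) {
  set.seed(seed)
  z <- rnorm(length(x))
  z <- residuals(lm(z ~ x))
  r * scale(x)[, 1] + sqrt(1 - r^2) * scale(z)[, 1]
}

# whole-image rows plus a compartment twin at exact correlation r
longPairAcc <- function(x, r, feature = "density__broad__T") {
  n <- length(x)
  rbind(
    data.frame(fov_id = paste0("f", 1:n), feature_name = feature,
               compartment = "whole_image", value = x,
               category = "density", cell_types = "T", markers = "",
               reason = NA_character_),
    data.frame(fov_id = paste0("f", 1:n), feature_name = feature,
               compartment = "cancer_core", value = correlatedVector(x, r),
               category = "density", cell_types = "T", markers = "",
               reason = NA_character_))
}
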