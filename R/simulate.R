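# Synthetic cohorts with known ground truth. A geometric tissue model — a
# cancer region (one or more discs) with a stromal surround — is populated
# with cells by Poisson sampling per region and type; cells are rendered as
# non-overlapping discs into label images, and channel images are rendered
# from per-cell marker intensities plus noise. Patient-level latent factors
# (immune infiltration, infiltrate mixing, marker positivity) perturb the
# generative parameters and drive a logistic outcome model, so downstream
# feature, importance and model estimates can be checked against truth.

#' Default synthetic cell-type hierarchy
#'
#' Eight broad types resolving to fourteen intermediate and twenty detailed
#' labels, mimicking the shape of a typical multiplexed-imaging phenotyping
#' hierarchy.
#'
#' @export
defaultHierarchy <- function() {
  clusterHierarchy(data.frame(
    detailed = c("Tumor_ECAD", "Tumor_CK17", "Tumor_Other",
                 "CD8T_exh", "CD8T_eff", "CD4T_conv", "Treg",
                 "Bcell_naive", "Bcell_mem",
                 "CD68_Mac_act", "CD68_Mac_rest", "CD163_Mac", "DC", "Mono",
                 "NKcell", "Neutrophil", "Fibroblast_1", "Fibroblast_2",
                 "Endo_vessel", "Other_cell"),
    intermediate = c("Tumor_ECAD", "Tumor_CK17", "Tumor_Other",
                     "CD8T", "CD8T", "CD4T", "Treg", "Bcell", "Bcell",
                     "CD68_Mac", "CD68_Mac", "CD163_Mac", "DC", "Mono",
                     "NK", "Neutrophil", "Fibroblast", "Fibroblast",
                     "Endothelium", "Other_int"),
    broad = c("Cancer", "Cancer", "Cancer",
              "T", "T", "T", "T", "B", "B",
              "Mono_Mac", "Mono_Mac", "Mono_Mac", "Mono_Mac", "Mono_Mac",
              "NK", "Granulocyte", "Stroma", "Stroma", "Stroma", "Other")))
}

.defaultDensities <- function() {
  # cells/px^2 at the intermediate level, cancer region vs stromal surround;
  # totals give a few hundred to ~2000 cells in a 512-1024 px FOV, matching
  # the cell-count range seen in segmented multiplexed images
  inter <- c("Tumor_ECAD", "Tumor_CK17", "Tumor_Other", "CD8T", "CD4T",
             "Treg", "Bcell", "CD68_Mac", "CD163_Mac", "DC", "Mono", "NK",
             "Neutrophil", "Fibroblast", "Endothelium", "Other_int")
  cancer <- c(6e-4, 3e-4, 1.5e-4, 0, 0, 0, 0, 0, 0,
              0, 0, 0, 0, 2.5e-5, 1.5e-5, 8e-6)
  stroma <- c(8e-6, 4e-6, 3e-6, 7e-5, 6e-5, 2.5e-5, 3.5e-5, 7e-5, 5e-5,
              1.2e-5, 2.5e-5, 1e-5, 1.5e-5, 2.5e-4, 8e-5, 2.5e-5)
  list(cancer = setNames(cancer, inter), stroma = setNames(stroma, inter))
}

.defaultMarkerProbs <- function() list(
  PD1   = c(CD8T = 0.30, CD4T = 0.15, Treg = 0.20, default = 0.02),
  PDL1  = c(Tumor_ECAD = 0.25, Tumor_CK17 = 0.25, Tumor_Other = 0.20,
            CD68_Mac = 0.35, CD163_Mac = 0.30, default = 0.03),
  Ki67  = c(Tumor_ECAD = 0.40, Tumor_CK17 = 0.35, Tumor_Other = 0.30,
            CD8T = 0.15, Bcell = 0.10, default = 0.05),
  TIM3  = c(CD8T = 0.20, NK = 0.15, default = 0.02),
  IDO   = c(DC = 0.25, CD68_Mac = 0.15, default = 0.02))

#' Build a simulation configuration
#'
#' Defaults describe a small serially sampled cohort: multi-FOV samples at
#' paired timepoints, a disc-shaped cancer region in a stromal surround,
#' realistic per-type densities, and patient latent factors (standard-normal
#' scores) that scale immune infiltration, infiltrate mixing and marker
#' positivity and feed a logistic outcome model.
#'
#' @param nPatients number of patients (default 20)
#' @param timepoints timepoints sampled per patient
#' @param fovsPerSample FOVs per (patient, timepoint)
#' @param fovSize FOV edge in px (default 512)
#' @param cancerRadiusRange min/max cancer-disc radius in px
#' @param nCancerRegions cancer discs per FOV
#' @param densities list with named vectors \code{cancer} and \code{stroma}
#'   of per-intermediate-type intensities (cells/px^2)
#' @param mixing baseline interleaving of the immune infiltrate with the
#'   cancer region: 0 = fully excluded, 1 = distributed as if spatially
#'   uniform over the whole FOV
#' @param cellRadiusRange min/max rendered cell radius in px
#' @param markerProbs per-marker named positivity probabilities by
#'   intermediate type (a \code{default} entry covers the rest)
#' @param markerIntensity c(pos_mean, pos_sd, neg_mean, neg_sd) of marker
#'   intensity (counts/px) given positivity status
#' @param outcome list(intercept, coefficients) - named logistic coefficients
#'   on the patient latents \code{immune_infiltration}, \code{mixing} and/or
#'   \code{marker_<name>}
#' @param latentTimepoints optional named list restricting a latent to some
#'   timepoints (e.g. an on-treatment-only effect); latents not listed act
#'   at every timepoint
#' @param hierarchy a \linkS4class{ClusterHierarchy}
#' @param renderImages also render label and channel images (slower)
#' @param noiseSd additive channel-noise SD (counts/px)
#' @param seed base RNG seed; a fixed seed makes every output identical
#' @return a \code{SimConfig} list
#' @export
simConfig <- function(nPatients = 20,
                      timepoints = c("baseline", "on_nivo"),
                      fovsPerSample = 2, fovSize = 512,
                      cancerRadiusRange = c(110, 170), nCancerRegions = 1,
                      densities = .defaultDensities(), mixing = 0.15,
                      cellRadiusRange = c(4, 8),
                      markerProbs = .defaultMarkerProbs(),
                      markerIntensity = c(pos_mean = 2, pos_sd = 0.5,
                                          neg_mean = 0.2, neg_sd = 0.1),
                      outcome = list(intercept = 0, coefficients = c(
                        immune_infiltration = 1.2, mixing = 0.8)),
                      hierarchy = defaultHierarchy(),
                      latentTimepoints = list(),
                      renderImages = FALSE, noiseSd = 0.05, seed = 1) {
  stopifnot(mixing >= 0, mixing <= 1, all(unlist(densities) >= 0),
            all(timepoints %in% TIMEPOINTS))
  for (mp in markerProbs) stopifnot(all(mp >= 0 & mp <= 1))
  structure(list(nPatients = nPatients, timepoints = timepoints,
                 fovsPerSample = fovsPerSample, fovSize = fovSize,
                 cancerRadiusRange = cancerRadiusRange,
                 nCancerRegions = nCancerRegions, densities = densities,
                 mixing = mixing, cellRadiusRange = cellRadiusRange,
                 markerProbs = markerProbs, markerIntensity = markerIntensity,
                 outcome = outcome, hierarchy = hierarchy,
                 latentTimepoints = latentTimepoints,
                 renderImages = renderImages, noiseSd = noiseSd, seed = seed),
            class = "SimConfig")
}

# dart-throwing placement of n non-overlapping discs inside a region;
# larger discs first, which packs noticeably better
.placeCells <- function(n, inRegion, size, radii, placed, maxTries = 100) {
  radii <- sort(radii, decreasing = TRUE)
  xs <- numeric(n); ys <- numeric(n); ok <- logical(n)
  px <- placed$x; py <- placed$y; pr <- placed$r
  for (i in seq_len(n)) {
    for (try in seq_len(maxTries)) {
      x <- runif(1, 0, size - 1); y <- runif(1, 0, size - 1)
      if (!inRegion(x, y)) next
      if (length(px) &&
          any((px - x)^2 + (py - y)^2 < (pr + radii[i])^2)) next
      xs[i] <- x; ys[i] <- y; ok[i] <- TRUE
      px <- c(px, x); py <- c(py, y); pr <- c(pr, radii[i])
      break
    }
    if (!ok[i])
      stop("generation error: could not place cells without overlap; ",
           "lower the densities or the cell radii")
  }
  list(x = xs, y = ys, r = radii, all = list(x = px, y = py, r = pr))
}

#' Simulate one FOV
#'
#' Poisson cell counts per (region, intermediate type); uniform placement of
#' non-overlapping discs inside the region; marker intensities drawn from
#' the positivity model; optional rendering of the label image and channel
#' images (cancer channel ECAD, functional markers, and the three ECM
#' channels).
#'
#' @param cfg a \code{SimConfig}
#' @param patient patient id
#' @param timepoint timepoint label
#' @param fovId FOV id
#' @param latents named patient latent scores (standard normal); missing
#'   entries default to 0
#' @return list: \code{cells} data.frame, \code{labels} integer matrix or
#'   NULL, \code{images} named list of channel matrices or NULL
#' @export
simulateFov <- function(cfg, patient, timepoint, fovId, latents = c()) {
  size <- cfg$fovSize
  lat <- function(nm) if (nm %in% names(latents)) latents[[nm]] else 0
  # cancer geometry
  nReg <- cfg$nCancerRegions
  cx <- runif(nReg, size * 0.3, size * 0.7)
  cy <- runif(nReg, size * 0.3, size * 0.7)
  cr <- runif(nReg, cfg$cancerRadiusRange[1], cfg$cancerRadiusRange[2])
  inCancer <- function(x, y) any((x - cx)^2 + (y - cy)^2 <= cr^2)
  cancerArea <- sum(pi * cr^2)  # mild overestimate if discs overlap
  stromaArea <- size^2 - cancerArea

  infil <- exp(0.5 * lat("immune_infiltration"))
  mixP <- if (cfg$mixing <= 0 && lat("mixing") == 0) 0 else
    stats::plogis(stats::qlogis(min(max(cfg$mixing, 0.01), 0.99)) +
                  0.8 * lat("mixing"))
  hier <- cfg$hierarchy
  im <- unique(hier@map[, c("intermediate", "broad")])
  types <- names(cfg$densities$stroma)
  rows <- list()
  placed <- list(x = numeric(), y = numeric(), r = numeric())
  for (ty in types) {
    broad <- im$broad[match(ty, im$intermediate)]
    immune <- broad %in% c("T", "B", "Mono_Mac", "NK", "Granulocyte")
    if (immune) {
      # mixing interpolates the infiltrate between full exclusion from the
      # cancer region (0) and a spatially uniform distribution (1)
      nTot <- rpois(1, cfg$densities$stroma[[ty]] * infil *
                      (stromaArea + cancerArea))
      nC <- rbinom(1, nTot, mixP * cancerArea / (stromaArea + cancerArea))
      nS <- nTot - nC
    } else {
      nC <- rpois(1, cfg$densities$cancer[[ty]] * cancerArea)
      nS <- rpois(1, cfg$densities$stroma[[ty]] * stromaArea)
    }
    for (reg in c("cancer", "stroma")) {
      n <- if (reg == "cancer") nC else nS
      if (n == 0) next
      radii <- runif(n, cfg$cellRadiusRange[1], cfg$cellRadiusRange[2])
      inReg <- if (reg == "cancer") inCancer
               else function(x, y) !inCancer(x, y)
      pl <- .placeCells(n, inReg, size, radii, placed)
      placed <- pl$all
      rows[[length(rows) + 1L]] <- data.frame(
        centroid_x = pl$x, centroid_y = pl$y, radius = pl$r,
        cluster_intermediate = ty, stringsAsFactors = FALSE)
    }
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(centroid_x = numeric(), centroid_y = numeric(),
               radius = numeric(), cluster_intermediate = character())
  n <- nrow(cells)
  if (n > 0) {
    ord <- order(cells$centroid_y, cells$centroid_x)
    cells <- cells[ord, , drop = FALSE]
  }
  cells$cell_id <- seq_len(n)
  cells$patient_id <- rep(patient, n)
  cells$timepoint <- rep(timepoint, n)
  cells$fov_id <- rep(fovId, n)
  cells$cell_area <- round(pi * cells$radius^2)
  # map intermediate -> detailed (first detailed child) and broad
  det <- hier@map
  firstDet <- vapply(cells$cluster_intermediate, function(ty)
    det$detailed[match(ty, det$intermediate)], "")
  cells$cluster_detailed <- firstDet
  cells$cluster_broad <- resolveLabel(hier, cells$cluster_intermediate,
                                      "broad")
  # morphology shape metric for cancer cells (and everyone): elongation
  cells$elongation <- pmax(rnorm(n, 1.3, 0.15), 1)
  # marker positivity + intensities
  mi <- cfg$markerIntensity
  for (mk in names(cfg$markerProbs)) {
    probs <- cfg$markerProbs[[mk]]
    p <- probs[cells$cluster_intermediate]
    p[is.na(p)] <- probs[["default"]]
    shift <- lat(paste0("marker_", mk))
    if (shift != 0) p <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-4),
                                                          1 - 1e-4)) + 0.8 * shift)
    pos <- runif(n) < p
    val <- ifelse(pos,
                  pmax(rnorm(n, mi[["pos_mean"]], mi[["pos_sd"]]), 0),
                  pmax(rnorm(n, mi[["neg_mean"]], mi[["neg_sd"]]), 0))
    cells[[mk]] <- val
  }
  labels <- NULL; images <- NULL
  if (cfg$renderImages) {
    labels <- matrix(0L, size, size)
    chans <- c("ECAD", names(cfg$markerProbs), "Collagen1", "Fibronectin",
               "FAP")
    images <- setNames(lapply(chans, function(z)
      pmax(matrix(rnorm(size * size, 0, cfg$noiseSd), size, size), 0)),
      chans)
    # stromal ECM fields: collagen everywhere outside the tumor; hot-ECM
    # components scale with the mixing latent for variety
    stromaField <- outer(0:(size - 1), 0:(size - 1), function(r, c)
      !inCancerVec(c, r, cx, cy, cr))
    images$Collagen1 <- images$Collagen1 + 0.8 * stromaField
    hot <- 0.4 * stats::plogis(lat("mixing"))
    images$Fibronectin <- images$Fibronectin + hot * stromaField
    images$FAP <- images$FAP + 0.5 * hot * stromaField
    for (i in seq_len(n)) {
      xi <- round(cells$centroid_x[i]); yi <- round(cells$centroid_y[i])
      r <- cells$radius[i]
      rr <- max(yi - floor(r), 0):min(yi + floor(r), size - 1)
      cc <- max(xi - floor(r), 0):min(xi + floor(r), size - 1)
      blk <- outer(rr, cc, function(a, b) (a - yi)^2 + (b - xi)^2 <= r^2)
      sub <- labels[rr + 1, cc + 1]
      sub[blk & sub == 0L] <- i
      labels[rr + 1, cc + 1] <- sub
      if (cells$cluster_broad[i] == "Cancer")
        images$ECAD[rr + 1, cc + 1] <- images$ECAD[rr + 1, cc + 1] + 1.5 * blk
      for (mk in names(cfg$markerProbs))
        images[[mk]][rr + 1, cc + 1] <-
          images[[mk]][rr + 1, cc + 1] + cells[[mk]][i] * blk
    }
  }
  cols <- c("patient_id", "timepoint", "fov_id", "cell_id", "centroid_x",
            "centroid_y", "cell_area", "cluster_detailed",
            "cluster_intermediate", "cluster_broad", "elongation",
            names(cfg$markerProbs))
  list(cells = cells[, cols], labels = labels, images = images)
}

# vectorized membership helper used for image fields
inCancerVec <- function(x, y, cx, cy, cr) {
  out <- rep(FALSE, length(x))
  for (k in seq_along(cx)) out <- out | ((x - cx[k])^2 + (y - cy[k])^2 <= cr[k]^2)
  out
}

#' Simulate a cohort with known ground truth
#'
#' Draws per-patient latent scores for every coefficient named in the
#' outcome model, generates all FOVs, and draws each patient's binary
#' response from the logistic model on the latents.
#'
#' @param cfg a \code{SimConfig}
#' @return list: \code{cellTable} (a \linkS4class{CellTable}),
#'   \code{labels} (patient_id, response), \code{fovMeta} (fov_id,
#'   patient_id, timepoint), \code{groundTruth} (latents, linear predictor,
#'   response probability per patient), and, when images are rendered,
#'   \code{labelImages} and \code{images} named by fov_id
#' @export
simulateCohort <- function(cfg) {
  set.seed(cfg$seed)
  coefs <- cfg$outcome$coefficients
  if (is.null(coefs)) coefs <- numeric()
  latents <- matrix(rnorm(cfg$nPatients * length(coefs)),
                    cfg$nPatients, length(coefs),
                    dimnames = list(NULL, names(coefs)))
  eta <- cfg$outcome$intercept +
    if (length(coefs)) as.numeric(latents %*% coefs) else 0
  prob <- stats::plogis(eta)
  response <- rbinom(cfg$nPatients, 1, prob)
  pats <- sprintf("P%03d", seq_len(cfg$nPatients))
  allCells <- list(); labelImages <- list(); images <- list()
  fovMeta <- list()
  for (pi in seq_len(cfg$nPatients)) {
    for (tp in cfg$timepoints) {
      for (f in seq_len(cfg$fovsPerSample)) {
        fid <- paste(pats[pi], tp, paste0("fov", f), sep = "_")
        lat <- latents[pi, ]
        for (nm in names(cfg$latentTimepoints))
          if (!tp %in% cfg$latentTimepoints[[nm]]) lat[nm] <- 0
        sim <- simulateFov(cfg, pats[pi], tp, fid, latents = lat)
        allCells[[fid]] <- sim$cells
        if (!is.null(sim$labels)) labelImages[[fid]] <- sim$labels
        if (!is.null(sim$images)) images[[fid]] <- sim$images
        fovMeta[[fid]] <- data.frame(fov_id = fid, patient_id = pats[pi],
                                     timepoint = tp, stringsAsFactors = FALSE)
      }
    }
  }
  cellsAll <- do.call(rbind, allCells)
  rownames(cellsAll) <- NULL
  fovMeta <- do.call(rbind, fovMeta)
  rownames(fovMeta) <- NULL
  fovInfo <- data.frame(fov_id = fovMeta$fov_id, width = cfg$fovSize,
                        height = cfg$fovSize, stringsAsFactors = FALSE)
  ct <- cellTable(cellsAll, cfg$hierarchy,
                  markers = names(cfg$markerProbs),
                  morphology = "elongation", fovInfo = fovInfo)
  gt <- data.frame(patient_id = pats, latents, eta = eta, prob = prob,
                   response = response, stringsAsFactors = FALSE)
  out <- list(cellTable = ct,
              labels = data.frame(patient_id = pats, response = response,
                                  stringsAsFactors = FALSE),
              fovMeta = fovMeta, groundTruth = gt)
  if (cfg$renderImages) {
    out$labelImages <- labelImages
    out$images <- images
  }
  out
}

#' Simulate a sample-by-feature cohort directly
#'
#' Matrix-level generator for calibration studies of the statistics and
#' model modules: standard-normal noise features with either a mean-shift
#' ("shift": planted features move by \code{effect} SD in responders, labels
#' drawn fair-coin first) or a logistic ("logistic": response drawn from
#' \code{plogis(beta * rowSums(planted))}) outcome.
#'
#' @param nPatients,nFeatures cohort dimensions
#' @param nPlanted number of signal features (0 = pure noise)
#' @param effect mean shift in SD units (shift model)
#' @param beta per-feature logistic coefficient (logistic model)
#' @param model "shift" or "logistic"
#' @param timepoint timepoint label given to all samples
#' @param seed RNG seed
#' @return list: \code{fm} (a \linkS4class{FeatureMatrix}), \code{labels},
#'   \code{planted} (feature names carrying signal)
#' @export
simulateFeatureCohort <- function(nPatients, nFeatures, nPlanted = 0,
                                  effect = 1.5, beta = 2,
                                  model = c("shift", "logistic"),
                                  timepoint = "baseline", seed = 1) {
  model <- match.arg(model)
  set.seed(seed)
  x <- matrix(rnorm(nPatients * nFeatures), nPatients, nFeatures)
  colnames(x) <- sprintf("feat_%03d::whole_image", seq_len(nFeatures))
  planted <- if (nPlanted > 0) colnames(x)[seq_len(nPlanted)] else character()
  if (model == "shift") {
    y <- rbinom(nPatients, 1, 0.5)
    if (nPlanted > 0)
      x[, seq_len(nPlanted)] <- x[, seq_len(nPlanted)] + effect * y
  } else {
    eta <- if (nPlanted > 0)
      beta * rowSums(x[, seq_len(nPlanted), drop = FALSE])
    else rep(0, nPatients)
    y <- rbinom(nPatients, 1, stats::plogis(eta))
  }
  pats <- sprintf("P%03d", seq_len(nPatients))
  rownames(x) <- paste(pats, timepoint, sep = "||")
  fm <- new("FeatureMatrix", values = x,
            sampleInfo = data.frame(patient_id = pats, timepoint = timepoint,
                                    stringsAsFactors = FALSE),
            featureInfo = data.frame(column = colnames(x),
              feature_name = sub("::.*$", "", colnames(x)),
              compartment = WHOLE_IMAGE, category = NA_character_,
              cell_types = "", markers = "", stringsAsFactors = FALSE))
  list(fm = fm, labels = data.frame(patient_id = pats, response = y,
                                    stringsAsFactors = FALSE),
       planted = planted)
}
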