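# Per-FOV feature classes: densities, density ratios, proportions, marker
# positivity frequencies, morphology, abundance and neighbor diversity,
# nearest cell-cell distances, mixing scores, k-means cellular neighborhoods
# and tile-level ECM clusters. computeFeatureCatalog() orchestrates the whole
# catalog over a cohort, including the two cohort-level admission filters
# (marker prevalence, distance/density correlation).

.featRows <- function(fov, name, compartment, value, category,
                      cell_types = "", markers = "", reason = NA_character_) {
  n <- max(length(name), length(value), length(compartment))
  data.frame(fov_id = rep_len(fov, n), feature_name = rep_len(name, n),
             compartment = rep_len(compartment, n), value = rep_len(value, n),
             category = rep_len(category, n),
             cell_types = rep_len(cell_types, n),
             markers = rep_len(markers, n),
             reason = rep_len(reason, n), stringsAsFactors = FALSE)
}

# region list for one FOV: whole image plus compartments when masks exist.
# Each region: cells (data.frame) and area (px^2, NA when unknown).
.fovRegions <- function(cellsub, areaWhole, compAreas = NULL) {
  regions <- list(whole_image = list(cells = cellsub, area = areaWhole))
  if (!is.null(compAreas)) {
    for (cp in COMPARTMENTS) {
      regions[[cp]] <- list(
        cells = cellsub[!is.null(cellsub$compartment) &
                        cellsub$compartment == cp, , drop = FALSE],
        area = compAreas[[cp]])
    }
  }
  regions
}

#' Default biologically motivated intermediate-level density-ratio pairs
#' @export
DEFAULT_INTERMEDIATE_PAIRS <- list(
  c("CD8T", "CD4T"), c("CD4T", "Treg"), c("CD8T", "Treg"),
  c("CD68_Mac", "CD163_Mac"))

#' Cell-type densities for one FOV
#'
#' Count divided by region area (cells per px^2), per cell type at the given
#' hierarchy level, for the whole image and each compartment present.
#' Zero-area regions yield missing values with reason \code{zero_area}.
#'
#' @param regions region list from the catalog driver (or build one via a
#'   single whole-image entry)
#' @param fov FOV id
#' @param level hierarchy level ("broad" or "intermediate")
#' @param typeLevels all type labels at that level
#' @return feature rows
#' @export
cellDensities <- function(regions, fov, level, typeLevels) {
  out <- list()
  for (rn in names(regions)) {
    r <- regions[[rn]]
    cnt <- table(factor(r$cells[[paste0("cluster_", level)]],
                        levels = typeLevels))
    ok <- !is.na(r$area) && r$area > 0
    out[[rn]] <- .featRows(fov, paste0("density__", level, "__", typeLevels),
      rn, if (ok) as.numeric(cnt) / r$area else NA_real_,
      "density", cell_types = typeLevels,
      reason = if (ok) NA_character_ else "zero_area")
  }
  do.call(rbind, out)
}

#' Density ratios with a minimum-density floor
#'
#' log2 ratio of two densities. A member below \code{minDensity} (default
#' 5e-7 cells/px^2) is rounded up to it; when both members are below the
#' floor the ratio is not calculated (reason \code{undefined_ratio}).
#'
#' @param densityRows output of \code{\link{cellDensities}} for one FOV
#' @param fov FOV id
#' @param level hierarchy level of the pair
#' @param pairs list of c(typeA, typeB) pairs
#' @param minDensity floor in cells/px^2
#' @export
densityRatioFeatures <- function(densityRows, fov, level, pairs,
                                 minDensity = 5e-7) {
  out <- list()
  for (rn in unique(densityRows$compartment)) {
    sub <- densityRows[densityRows$compartment == rn, ]
    dens <- setNames(sub$value, sub$cell_types)
    for (pr in pairs) {
      nm <- paste0("density_ratio__", level, "__", pr[1], "__", pr[2])
      a <- dens[[pr[1]]]; b <- dens[[pr[2]]]
      if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) {
        val <- NA_real_; reason <- "zero_area"
      } else if (a < minDensity && b < minDensity) {
        val <- NA_real_; reason <- "undefined_ratio"
      } else {
        val <- log2(max(a, minDensity) / max(b, minDensity))
        reason <- NA_character_
      }
      out[[length(out) + 1L]] <- .featRows(fov, nm, rn, val, "density_ratio",
        cell_types = paste(pr, collapse = ";"), reason = reason)
    }
  }
  do.call(rbind, out)
}

#' Intermediate-within-broad cell-type proportions
#'
#' For each broad type with at least two intermediate children, the fraction
#' of the broad count contributed by each child, per region.
#'
#' @param regions region list
#' @param fov FOV id
#' @param hier a \linkS4class{ClusterHierarchy}
#' @export
proportionFeatures <- function(regions, fov, hier) {
  im <- unique(hier@map[, c("intermediate", "broad")])
  parents <- names(which(table(im$broad) >= 2))
  out <- list()
  for (rn in names(regions)) {
    cl <- regions[[rn]]$cells
    for (p in parents) {
      children <- im$intermediate[im$broad == p]
      nb <- sum(cl$cluster_broad == p)
      cnt <- table(factor(cl$cluster_intermediate, levels = children))
      out[[length(out) + 1L]] <- .featRows(fov,
        paste0("proportion__", children, "__of__", p), rn,
        if (nb > 0) as.numeric(cnt) / nb else NA_real_,
        "density_proportion", cell_types = paste0(children, ";", p),
        reason = if (nb > 0) NA_character_ else "no_cells")
    }
  }
  do.call(rbind, out)
}

#' Functional-marker positivity frequencies
#'
#' Per (intermediate cell type, marker): the fraction of that type's cells
#' with intensity strictly above the marker threshold. FOVs with fewer than
#' \code{minCells} cells of the type are missing with reason
#' \code{below_min_cells}. Cohort-wide admission (the prevalence floor) is
#' applied by the catalog driver, not here.
#'
#' @param regions region list
#' @param fov FOV id
#' @param types intermediate type labels
#' @param thresholds named positivity thresholds
#' @param minCells per-FOV minimum cell count (default 5)
#' @param compartments compute per-compartment rows too (default FALSE:
#'   whole-image only)
#' @export
markerFrequencyFeatures <- function(regions, fov, types, thresholds,
                                    minCells = 5, compartments = FALSE) {
  if (!compartments) regions <- regions["whole_image"]
  out <- list()
  for (rn in names(regions)) {
    cl <- regions[[rn]]$cells
    for (ty in types) {
      sub <- cl[cl$cluster_intermediate == ty, , drop = FALSE]
      enough <- nrow(sub) >= minCells
      for (mk in names(thresholds)) {
        out[[length(out) + 1L]] <- .featRows(fov,
          paste0("marker_pos__", ty, "__", mk), rn,
          if (enough) mean(sub[[mk]] > thresholds[[mk]]) else NA_real_,
          "marker_positivity", cell_types = ty, markers = mk,
          reason = if (enough) NA_character_ else "below_min_cells")
      }
    }
  }
  do.call(rbind, out)
}

#' Morphology features
#'
#' Whole-image mean cell size per intermediate type, plus the mean of the
#' configured non-redundant shape metrics for cancer cells only.
#'
#' @param cellsub one FOV's cells
#' @param fov FOV id
#' @param types intermediate type labels
#' @param cfg a \linkS4class{PanelConfig}
#' @export
morphologyFeatures <- function(cellsub, fov, types, cfg) {
  out <- list()
  for (ty in types) {
    a <- cellsub$cell_area[cellsub$cluster_intermediate == ty]
    out[[length(out) + 1L]] <- .featRows(fov, paste0("size__", ty),
      WHOLE_IMAGE, if (length(a)) mean(a) else NA_real_, "morphology",
      cell_types = ty, reason = if (length(a)) NA_character_ else "no_cells")
  }
  cc <- cellsub[cellsub$cluster_broad == cfg@cancerLabel, , drop = FALSE]
  for (mcol in intersect(cfg@cancerMorphology, names(cellsub))) {
    out[[length(out) + 1L]] <- .featRows(fov,
      paste0("morph__", mcol, "__cancer"), WHOLE_IMAGE,
      if (nrow(cc)) mean(cc[[mcol]]) else NA_real_, "morphology",
      cell_types = cfg@cancerLabel,
      reason = if (nrow(cc)) NA_character_ else "no_cells")
  }
  do.call(rbind, out)
}

#' Abundance-based Shannon diversity
#'
#' Shannon index of the cell-type proportions, at the broad level over all
#' cells and at the intermediate level within each configured super-group of
#' broad types (by default, within every broad parent with >= 2 children),
#' per region.
#'
#' @param regions region list
#' @param fov FOV id
#' @param hier a \linkS4class{ClusterHierarchy}
#' @param superGroups named list mapping group name -> broad labels; empty
#'   list means one group per multi-child broad parent
#' @export
abundanceDiversityFeatures <- function(regions, fov, hier,
                                       superGroups = list()) {
  im <- unique(hier@map[, c("intermediate", "broad")])
  if (!length(superGroups)) {
    parents <- names(which(table(im$broad) >= 2))
    superGroups <- setNames(as.list(parents), parents)
  }
  out <- list()
  for (rn in names(regions)) {
    cl <- regions[[rn]]$cells
    h <- if (nrow(cl)) shannonIndex(table(cl$cluster_broad)) else NA_real_
    out[[length(out) + 1L]] <- .featRows(fov, "diversity__broad", rn, h,
      "diversity_abundance",
      reason = if (is.na(h)) "no_cells" else NA_character_)
    for (g in names(superGroups)) {
      sel <- cl$cluster_broad %in% superGroups[[g]]
      h <- if (any(sel)) shannonIndex(table(cl$cluster_intermediate[sel]))
           else NA_real_
      out[[length(out) + 1L]] <- .featRows(fov,
        paste0("diversity__intermediate__", g), rn, h, "diversity_abundance",
        cell_types = paste(superGroups[[g]], collapse = ";"),
        reason = if (is.na(h)) "no_cells" else NA_character_)
    }
  }
  do.call(rbind, out)
}

#' Neighborhood Shannon diversity
#'
#' Per-cell Shannon index of the intermediate-type composition within the
#' neighbor radius, averaged per index-cell type. Cells with no neighbors
#' are skipped. Compartment rows group index cells by their compartment.
#'
#' @param cellsub one FOV's cells (with a \code{compartment} column when
#'   compartment rows are wanted)
#' @param counts neighbor count matrix from \code{\link{neighborCounts}} at
#'   the intermediate level
#' @param fov FOV id
#' @param types intermediate type labels to report
#' @param compartments emit per-compartment rows
#' @export
neighborDiversityFeatures <- function(cellsub, counts, fov, types,
                                      compartments = FALSE) {
  perCell <- apply(counts, 1, shannonIndex)
  hasNb <- rowSums(counts) > 0
  groups <- list(whole_image = rep(TRUE, nrow(cellsub)))
  if (compartments && !is.null(cellsub$compartment))
    for (cp in COMPARTMENTS) groups[[cp]] <- cellsub$compartment == cp
  out <- list()
  for (rn in names(groups)) {
    for (ty in types) {
      sel <- groups[[rn]] & hasNb & cellsub$cluster_intermediate == ty
      out[[length(out) + 1L]] <- .featRows(fov,
        paste0("neighbor_diversity__", ty), rn,
        if (any(sel)) mean(perCell[sel]) else NA_real_, "diversity_neighbor",
        cell_types = ty, reason = if (any(sel)) NA_character_ else "no_cells")
    }
  }
  do.call(rbind, out)
}

#' Nearest-other-type distance features
#'
#' For each ordered pair of distinct broad types, the per-source-cell
#' distance to the nearest target cell anywhere in the FOV, averaged over
#' source cells (grouped by source-cell compartment for compartment rows).
#'
#' @param cellsub one FOV's cells
#' @param fov FOV id
#' @param typeLevels broad type labels
#' @param compartments emit per-compartment rows
#' @export
nearestDistanceFeatures <- function(cellsub, fov, typeLevels,
                                    compartments = FALSE) {
  xy <- cbind(cellsub$centroid_x, cellsub$centroid_y)
  groups <- list(whole_image = rep(TRUE, nrow(cellsub)))
  if (compartments && !is.null(cellsub$compartment))
    for (cp in COMPARTMENTS) groups[[cp]] <- cellsub$compartment == cp
  out <- list()
  for (src in typeLevels) for (tgt in setdiff(typeLevels, src)) {
    si <- which(cellsub$cluster_broad == src)
    ti <- which(cellsub$cluster_broad == tgt)
    nn <- rep(NA_real_, nrow(cellsub))
    if (length(si) && length(ti)) {
      d2 <- crossDist2(xy[si, , drop = FALSE], xy[ti, , drop = FALSE])
      nn[si] <- sqrt(apply(d2, 1, min))
    }
    nm <- paste0("distance__", src, "__to__", tgt)
    for (rn in names(groups)) {
      sel <- groups[[rn]] & !is.na(nn)
      out[[length(out) + 1L]] <- .featRows(fov, nm, rn,
        if (any(sel)) mean(nn[sel]) else NA_real_, "distance",
        cell_types = paste0(src, ";", tgt),
        reason = if (any(sel)) NA_character_ else "no_target")
    }
  }
  do.call(rbind, out)
}

#' Mixing-score features (whole image)
#'
#' All unordered broad-type pairs; see \code{\link{mixingScore}}.
#'
#' @param cellsub one FOV's cells
#' @param fov FOV id
#' @param typeLevels broad type labels
#' @param radius px
#' @param mode "pooled" or "percell"
#' @export
mixingScoreFeatures <- function(cellsub, fov, typeLevels, radius = 50,
                                mode = "pooled") {
  out <- list()
  n <- length(typeLevels)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- typeLevels[i]; b <- typeLevels[j]
    v <- mixingScore(cellsub, cellsub$cluster_broad, a, b,
                     radius = radius, mode = mode)
    out[[length(out) + 1L]] <- .featRows(fov,
      paste0("mixing__", a, "__", b), WHOLE_IMAGE, v, "mixing",
      cell_types = paste0(a, ";", b),
      reason = if (is.na(v)) "no_cells" else NA_character_)
  }
  do.call(rbind, out)
}

# deterministic relabeling of k-means clusters: order by dominant centroid
# column (lexical), then by decreasing dominant loading
.relabelKmeans <- function(centers) {
  dom <- colnames(centers)[max.col(centers, ties.method = "first")]
  order(dom, -apply(centers, 1, max))
}

#' Cohort-wide cellular neighborhoods
#'
#' k-means on per-cell neighbor-composition proportion vectors at the
#' intermediate level (cells with no neighbors excluded), with deterministic
#' cluster relabeling. Emits per-FOV proportions of cells in each
#' neighborhood (whole image and, when available, per compartment).
#'
#' @param cellsAll cohort cell data.frame with columns \code{fov_id},
#'   \code{cluster_intermediate}, centroid columns and optionally
#'   \code{compartment}
#' @param countsAll neighbor count matrix aligned to \code{cellsAll} rows
#' @param k number of neighborhoods (default 12)
#' @param seed RNG seed for k-means
#' @param compartments emit per-compartment rows
#' @return list: \code{features} rows, \code{assignment} per-cell neighborhood
#'   (NA for cells without neighbors), \code{centers} relabeled centroid matrix
#' @export
cellNeighborhoodFeatures <- function(cellsAll, countsAll, k = 12, seed = 42,
                                     compartments = FALSE) {
  hasNb <- rowSums(countsAll) > 0
  props <- countsAll[hasNb, , drop = FALSE] / rowSums(countsAll)[hasNb]
  if (nrow(props) < k)
    stop("clustering error: fewer cells with neighbors (", nrow(props),
         ") than clusters (", k, ")")
  km <- local({ set.seed(seed)
    kmeans(props, centers = k, nstart = 10, iter.max = 100) })
  ord <- .relabelKmeans(km$centers)
  newId <- match(km$cluster, ord)
  assignment <- rep(NA_integer_, nrow(cellsAll))
  assignment[hasNb] <- newId
  out <- list()
  for (fov in unique(cellsAll$fov_id)) {
    inFov <- cellsAll$fov_id == fov
    groups <- list(whole_image = inFov)
    if (compartments && !is.null(cellsAll$compartment))
      for (cp in COMPARTMENTS)
        groups[[cp]] <- inFov & cellsAll$compartment == cp
    for (rn in names(groups)) {
      sel <- groups[[rn]] & !is.na(assignment)
      tot <- sum(sel)
      cnt <- tabulate(assignment[sel], nbins = k)
      out[[length(out) + 1L]] <- .featRows(fov,
        paste0("neighborhood__", seq_len(k), "__prop"), rn,
        if (tot > 0) cnt / tot else NA_real_, "neighborhood",
        reason = if (tot > 0) NA_character_ else "no_cells")
    }
  }
  list(features = do.call(rbind, out), assignment = assignment,
       centers = km$centers[ord, , drop = FALSE])
}

#' Tile-level ECM clusters
#'
#' Images are cut into square tiles; a binary ECM mask is defined as pixels
#' where any smoothed ECM channel exceeds its threshold. Tiles with less than
#' \code{minFrac} ECM area are non-ECM; remaining tiles are described by each
#' marker's total expression normalized by the tile's ECM-mask area and
#' 2-means clustered cohort-wide into Cold (collagen-dominant, lower
#' non-collagen centroid) vs Hot (collagen plus fibronectin/FAP). Per FOV,
#' the proportions of Cold, Hot and non-ECM tiles are emitted (they sum to 1).
#'
#' @param imagesByFov named list (per FOV) of named lists of channel matrices
#' @param cfg a \linkS4class{PanelConfig} (uses \code{ecmChannels},
#'   \code{ecmThresholds}, \code{tile_size}, \code{ecm_min_frac},
#'   \code{ecm_smooth_sigma}, \code{kmeans_seed})
#' @return feature rows
#' @export
ecmTileFeatures <- function(imagesByFov, cfg) {
  chans <- cfg@ecmChannels
  tile <- panelParam(cfg, "tile_size")
  minFrac <- panelParam(cfg, "ecm_min_frac")
  sig <- panelParam(cfg, "ecm_smooth_sigma")
  tiles <- list(); tileFov <- character()
  for (fov in names(imagesByFov)) {
    imgs <- imagesByFov[[fov]]
    miss <- setdiff(chans, names(imgs))
    if (length(miss))
      stop("config error: missing ECM channel(s) ", paste(miss, collapse = ", "))
    sm <- lapply(imgs[chans], gaussianSmooth, sigma = sig)
    thr <- cfg@ecmThresholds[chans]
    ecmMask <- Reduce(`|`, Map(function(m, t) m > t, sm, as.list(thr)))
    dims <- dim(ecmMask)
    for (ty in seq_len(dims[1] %/% tile)) for (tx in seq_len(dims[2] %/% tile)) {
      ri <- ((ty - 1) * tile + 1):(ty * tile)
      ci <- ((tx - 1) * tile + 1):(tx * tile)
      maskArea <- sum(ecmMask[ri, ci])
      frac <- maskArea / (tile * tile)
      expr <- if (frac < minFrac) rep(NA_real_, length(chans)) else
        vapply(chans, function(ch) sum(imgs[[ch]][ri, ci]) / maskArea,
               numeric(1))
      tiles[[length(tiles) + 1L]] <- expr
      tileFov <- c(tileFov, fov)
    }
  }
  tm <- do.call(rbind, tiles)
  isEcm <- stats::complete.cases(tm)
  cl <- rep(NA_integer_, length(tileFov))
  if (sum(isEcm) >= 2) {
    km <- local({ set.seed(panelParam(cfg, "kmeans_seed"))
      kmeans(tm[isEcm, , drop = FALSE], centers = 2, nstart = 10) })
    nonCollagen <- rowSums(km$centers[, -1, drop = FALSE])
    cold <- which.min(nonCollagen)  # collagen-dominant cluster
    cl[isEcm] <- ifelse(km$cluster == cold, 1L, 2L)
  }
  out <- list()
  labs <- c("cold_collagen", "hot_collagen", "non_ecm")
  for (fov in names(imagesByFov)) {
    sel <- tileFov == fov
    n <- sum(sel)
    props <- c(sum(cl[sel] == 1L, na.rm = TRUE),
               sum(cl[sel] == 2L, na.rm = TRUE),
               sum(is.na(cl[sel]))) / n
    out[[length(out) + 1L]] <- .featRows(fov, paste0("ecm__", labs, "__prop"),
      WHOLE_IMAGE, props, "ecm", markers = paste(chans, collapse = ";"))
  }
  do.call(rbind, out)
}

# centroid-based compartment lookup when label images are unavailable
.centroidCompartment <- function(cellsub, maskSet) {
  dims <- dim(maskSet@background)
  code <- matrix(4L, dims[1], dims[2])  # default stroma_core
  for (k in seq_along(COMPARTMENTS)) code[maskSet@masks[[k]]] <- k
  code[maskSet@aggregates] <- 5L
  code[maskSet@background] <- 6L
  ij <- cbind(pmin(pmax(round(cellsub$centroid_y), 0), dims[1] - 1) + 1,
              pmin(pmax(round(cellsub$centroid_x), 0), dims[2] - 1) + 1)
  c(COMPARTMENTS, "immune_agg", "background")[code[ij]]
}

#' Compute the full feature catalog for a cohort
#'
#' Runs every feature class per FOV, then applies the two cohort-level
#' admission rules: functional markers must be positive in at least
#' \code{prevalence_floor} of a cell type's cells cohort-wide, and
#' nearest-distance features whose whole-image values correlate with the
#' target type's density beyond \code{distance_corr_cutoff} (|Pearson r|)
#' are dropped as abundance proxies.
#'
#' @param ct a \linkS4class{CellTable}
#' @param cfg a \linkS4class{PanelConfig}
#' @param maskSets optional named list (by fov_id) of
#'   \linkS4class{CompartmentMaskSet}; enables compartment-level features
#' @param labelsList optional named list of label matrices, used for
#'   maximum-overlap cell-to-compartment assignment (centroid lookup is the
#'   fallback)
#' @param images optional named list (by fov_id) of named channel-matrix
#'   lists; enables ECM tile features
#' @param markerCompartments also compute marker frequencies per compartment
#'   (off by default; whole-image is the reference definition)
#' @param mixingMode "pooled" (default) or "percell"
#' @param intermediatePairs intermediate-level density-ratio pairs; pairs
#'   with types absent from the hierarchy are skipped
#' @return a \linkS4class{FeatureCatalog}
#' @export
computeFeatureCatalog <- function(ct, cfg, maskSets = NULL, labelsList = NULL,
                                  images = NULL, markerCompartments = FALSE,
                                  mixingMode = c("pooled", "percell"),
                                  intermediatePairs = DEFAULT_INTERMEDIATE_PAIRS) {
  mixingMode <- match.arg(mixingMode)
  hier <- ct@hierarchy
  broadTypes <- hierarchyLevels(hier, "broad")
  interTypes <- hierarchyLevels(hier, "intermediate")
  radius <- panelParam(cfg, "neighbor_radius")
  thresholds <- cfg@thresholds
  fovs <- fovIds(ct)
  rowsList <- list()
  cellsAug <- list(); countsList <- list()

  for (fov in fovs) {
    cellsub <- fovCells(ct, fov)
    ms <- if (!is.null(maskSets)) maskSets[[fov]] else NULL
    compAreas <- NULL
    if (!is.null(ms)) {
      compAreas <- as.list(compartmentAreas(ms))
      lab <- if (!is.null(labelsList)) labelsList[[fov]] else NULL
      cellsub$compartment <- if (!is.null(lab)) assignCells(cellsub, lab, ms)
                             else .centroidCompartment(cellsub, ms)
      areaWhole <- sum(unlist(compAreas))
      rowsList[[length(rowsList) + 1L]] <- compartmentAreaFeatures(ms)
    } else {
      fi <- ct@fovInfo
      idx <- match(fov, fi$fov_id)
      if (is.na(idx))
        stop("no mask set and no fovInfo entry for FOV ", fov,
             ": image area unknown")
      areaWhole <- fi$width[idx] * fi$height[idx]
    }
    if (nrow(cellsub) == 0) next  # a FOV with no cells yields no cell features
    regions <- .fovRegions(cellsub, areaWhole, compAreas)
    compFlag <- !is.null(compAreas)

    dB <- cellDensities(regions, fov, "broad", broadTypes)
    dI <- cellDensities(regions, fov, "intermediate", interTypes)
    broadPairs <- list()
    for (i in seq_len(length(broadTypes) - 1))
      for (j in (i + 1):length(broadTypes))
        broadPairs[[length(broadPairs) + 1L]] <- c(broadTypes[i], broadTypes[j])
    ipairs <- Filter(function(p) all(p %in% interTypes), intermediatePairs)
    minD <- panelParam(cfg, "min_density")
    rowsList[[length(rowsList) + 1L]] <- dB
    rowsList[[length(rowsList) + 1L]] <- dI
    rowsList[[length(rowsList) + 1L]] <-
      densityRatioFeatures(dB, fov, "broad", broadPairs, minD)
    if (length(ipairs))
      rowsList[[length(rowsList) + 1L]] <-
        densityRatioFeatures(dI, fov, "intermediate", ipairs, minD)
    rowsList[[length(rowsList) + 1L]] <- proportionFeatures(regions, fov, hier)
    if (length(thresholds))
      rowsList[[length(rowsList) + 1L]] <- markerFrequencyFeatures(
        regions, fov, interTypes, thresholds,
        minCells = panelParam(cfg, "min_cells"),
        compartments = markerCompartments)
    rowsList[[length(rowsList) + 1L]] <-
      morphologyFeatures(cellsub, fov, interTypes, cfg)
    rowsList[[length(rowsList) + 1L]] <- abundanceDiversityFeatures(
      regions, fov, hier, superGroups = panelParam(cfg, "super_groups"))
    cnts <- neighborCounts(cellsub, cellsub$cluster_intermediate,
                           radius = radius, levels = interTypes)
    rowsList[[length(rowsList) + 1L]] <- neighborDiversityFeatures(
      cellsub, cnts, fov, interTypes, compartments = compFlag)
    rowsList[[length(rowsList) + 1L]] <- nearestDistanceFeatures(
      cellsub, fov, broadTypes, compartments = compFlag)
    rowsList[[length(rowsList) + 1L]] <- mixingScoreFeatures(
      cellsub, fov, broadTypes, radius = radius, mode = mixingMode)
    cellsAug[[fov]] <- cellsub
    countsList[[fov]] <- cnts
  }

  allCells <- do.call(rbind, cellsAug)
  if (!is.null(allCells) && nrow(allCells) > 0) {
    k <- panelParam(cfg, "n_neighborhoods")
    nb <- cellNeighborhoodFeatures(allCells, do.call(rbind, countsList),
      k = k, seed = panelParam(cfg, "kmeans_seed"),
      compartments = !is.null(maskSets))
    rowsList[[length(rowsList) + 1L]] <- nb$features
  }
  if (!is.null(images))
    rowsList[[length(rowsList) + 1L]] <- ecmTileFeatures(images, cfg)

  values <- do.call(rbind, rowsList)
  rownames(values) <- NULL
  cat_ <- new("FeatureCatalog", values = values)
  cat_ <- filterMarkerPrevalence(cat_, ct,
    floor = panelParam(cfg, "prevalence_floor"), thresholds = thresholds)
  filterDistanceDensity(cat_, cutoff = panelParam(cfg, "distance_corr_cutoff"))
}

#' @rdname computeFeatureCatalog
#' @param x a \linkS4class{FeatureCatalog}
#' @export
featureValues <- function(x) x@values

setMethod("show", "FeatureCatalog", function(object) {
  v <- object@values
  cat("FeatureCatalog:", length(unique(v$feature_name)), "features x",
      length(unique(v$fov_id)), "FOVs (", nrow(v), "rows,",
      sum(is.na(v$value)), "missing )\n")
})

#' Drop marker features below the cohort prevalence floor
#'
#' A (cell type, marker) pair is admitted only if the marker is positive in
#' at least \code{floor} of that type's cells across the whole cohort.
#'
#' @param catalog a \linkS4class{FeatureCatalog}
#' @param ct the cohort \linkS4class{CellTable}
#' @param floor cohort-wide prevalence fraction (default 0.05)
#' @param thresholds named positivity thresholds
#' @export
filterMarkerPrevalence <- function(catalog, ct, floor = 0.05,
                                   thresholds = numeric()) {
  if (!length(thresholds)) return(catalog)
  d <- ct@cells
  v <- catalog@values
  drop <- rep(FALSE, nrow(v))
  isMk <- v$category == "marker_positivity"
  for (ty in unique(v$cell_types[isMk])) {
    sub <- d[d$cluster_intermediate == ty, , drop = FALSE]
    for (mk in names(thresholds)) {
      prev <- if (nrow(sub)) mean(sub[[mk]] > thresholds[[mk]]) else 0
      if (prev < floor)
        drop <- drop | (isMk & v$cell_types == ty & v$markers == mk)
    }
  }
  new("FeatureCatalog", values = v[!drop, , drop = FALSE])
}

#' Drop distance features that proxy target abundance
#'
#' Removes (source, target) nearest-distance features whose whole-image
#' values correlate (|Pearson r| > cutoff, pairwise-complete, across FOVs)
#' with the target type's whole-image density; all compartment rows of a
#' dropped feature are removed too.
#'
#' @param catalog a \linkS4class{FeatureCatalog}
#' @param cutoff absolute correlation cutoff (default 0.7)
#' @export
filterDistanceDensity <- function(catalog, cutoff = 0.7) {
  v <- catalog@values
  dn <- v[v$category == "distance" & v$compartment == WHOLE_IMAGE, ]
  if (!nrow(dn)) return(catalog)
  dropNames <- character()
  for (nm in unique(dn$feature_name)) {
    tgt <- sub(".*__to__", "", nm)
    dsub <- dn[dn$feature_name == nm, ]
    dens <- v[v$feature_name == paste0("density__broad__", tgt) &
              v$compartment == WHOLE_IMAGE, ]
    m <- merge(dsub[, c("fov_id", "value")], dens[, c("fov_id", "value")],
               by = "fov_id")
    m <- m[complete.cases(m), ]
    if (nrow(m) >= 3 && sd(m$value.x) > 0 && sd(m$value.y) > 0 &&
        abs(cor(m$value.x, m$value.y)) > cutoff)
      dropNames <- c(dropNames, nm)
  }
  keep <- !(v$feature_name %in% dropNames)
  new("FeatureCatalog", values = v[keep, , drop = FALSE])
}
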