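# Tumor compartments: each FOV is split into cancer core, cancer border,
# stroma border and stroma core by eroding/dilating a cancer mask by a fixed
# radius (default 50 px), after removing slide background and immune
# aggregates. All morphology uses Euclidean distance transforms, i.e. a disc
# structuring element.

.fillSmallHoles <- function(mask, maxArea) {
  holes <- EBImage::bwlabel(!mask)
  if (max(holes) == 0) return(mask)
  border <- unique(c(holes[1, ], holes[nrow(holes), ],
                     holes[, 1], holes[, ncol(holes)]))
  sizes <- tabulate(holes, nbins = max(holes))
  fill <- setdiff(which(sizes < maxArea), border)
  mask | matrix(holes %in% fill, nrow(mask), ncol(mask))
}

.dropSmallComponents <- function(mask, minArea) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab, nbins = max(lab))
  matrix(lab %in% which(sizes >= minArea), nrow(mask), ncol(mask))
}

.erodeDisc <- function(mask, r) {
  if (!any(mask)) return(mask)
  # pad with a background ring so the image edge erodes like a mask boundary
  pad <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
  d <- matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(pad))),
              nrow(pad), ncol(pad))
  d[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] > r
}

.dilateDisc <- function(mask, r) {
  if (all(mask)) return(mask)
  d <- matrix(EBImage::imageData(EBImage::distmap(EBImage::Image((!mask) * 1))),
              nrow(mask), ncol(mask))
  mask | (d <= r)
}

#' Build the cancer mask for one FOV
#'
#' Union of (a) the smoothed, binarized cancer channel (ECAD by default) and
#' (b) the pixels of segmented cancer cells; small holes are filled and
#' components below the size cutoff removed.
#'
#' @param channel cancer-channel matrix (e.g. ECAD), or NULL to use cell
#'   segmentations alone
#' @param cells data.frame of this FOV's cells (needs \code{cell_id},
#'   \code{cluster_broad})
#' @param labels integer label matrix
#' @param cfg a \linkS4class{PanelConfig}
#' @return logical matrix
#' @export
buildCancerMask <- function(channel, cells, labels, cfg) {
  dims <- dim(labels)
  chanMask <- matrix(FALSE, dims[1], dims[2])
  if (!is.null(channel)) {
    if (!identical(dim(channel), dims))
      stop("config error: cancer channel shape does not match label image")
    sm <- gaussianSmooth(channel, panelParam(cfg, "smooth_sigma"))
    thr <- panelParam(cfg, "cancer_threshold")
    if (is.na(thr)) {
      rng <- range(sm)
      if (diff(rng) > 0) {
        thr01 <- EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng)),
                               range = c(0, 1))
        thr <- rng[1] + thr01 * diff(rng)
      } else thr <- Inf  # flat image: no signal-driven mask
    }
    chanMask <- sm > thr
  }
  cancerIds <- cells$cell_id[cells$cluster_broad == cfg@cancerLabel]
  cellMask <- matrix(labels %in% cancerIds, dims[1], dims[2])
  mask <- chanMask | cellMask
  if (!any(mask)) return(mask)
  mask <- .fillSmallHoles(mask, panelParam(cfg, "hole_fill"))
  .dropSmallComponents(mask, panelParam(cfg, "min_component"))
}

#' Slide-background mask
#'
#' Pixels where the smoothed sum of all channels falls below a threshold,
#' i.e. areas with no tissue.
#'
#' @param images named list of channel matrices
#' @param cfg a \linkS4class{PanelConfig}
#' @export
backgroundMask <- function(images, cfg) {
  total <- Reduce(`+`, images)
  gaussianSmooth(total, panelParam(cfg, "smooth_sigma")) <
    panelParam(cfg, "background_threshold")
}

#' Immune-aggregate mask
#'
#' Large clumps of T and/or B cells, detected as regions where a gaussian
#' kernel density estimate of their centroids exceeds a density threshold,
#' keeping components above a minimum area.
#'
#' @param cells data.frame of this FOV's cells
#' @param dims image dimensions c(nrow, ncol)
#' @param cfg a \linkS4class{PanelConfig}
#' @export
immuneAggregateMask <- function(cells, dims, cfg) {
  sel <- cells$cluster_broad %in% cfg@aggregateLabels
  raster <- matrix(0, dims[1], dims[2])
  if (any(sel)) {
    ij <- cbind(pmin(pmax(round(cells$centroid_y[sel]), 0), dims[1] - 1) + 1,
                pmin(pmax(round(cells$centroid_x[sel]), 0), dims[2] - 1) + 1)
    for (k in seq_len(nrow(ij)))
      raster[ij[k, 1], ij[k, 2]] <- raster[ij[k, 1], ij[k, 2]] + 1
  }
  dens <- gaussianSmooth(raster, panelParam(cfg, "aggregate_sigma"))
  .dropSmallComponents(dens > panelParam(cfg, "aggregate_density"),
                       panelParam(cfg, "aggregate_min_area"))
}

#' Derive the four compartments from a cancer mask
#'
#' cancer_core = cancer eroded by \code{radius}; cancer_border = the eroded
#' rim; stroma_border = the ring gained by dilating cancer by \code{radius};
#' stroma_core = everything else. Background and immune aggregates are then
#' removed from all four, so the six masks partition the FOV.
#'
#' @param cancerMask logical matrix
#' @param background logical matrix (slide background)
#' @param aggregates logical matrix (immune aggregates)
#' @param radius erosion/dilation radius in px (default 50)
#' @param fovId identifier stored in the result
#' @return a \linkS4class{CompartmentMaskSet}
#' @export
deriveCompartments <- function(cancerMask, background = NULL,
                               aggregates = NULL, radius = 50,
                               fovId = "fov") {
  stopifnot(radius > 0)
  dims <- dim(cancerMask)
  if (is.null(background)) background <- matrix(FALSE, dims[1], dims[2])
  if (is.null(aggregates)) aggregates <- matrix(FALSE, dims[1], dims[2])
  core <- .erodeDisc(cancerMask, radius)
  dilated <- .dilateDisc(cancerMask, radius)
  keep <- !background & !aggregates
  masks <- list(
    cancer_core   = core & keep,
    cancer_border = cancerMask & !core & keep,
    stroma_border = dilated & !cancerMask & keep,
    stroma_core   = !dilated & keep)
  new("CompartmentMaskSet", fovId = as.character(fovId), masks = masks,
      background = background & TRUE, aggregates = (aggregates & !background))
}

#' Build compartment mask sets for every FOV of a cohort
#'
#' Convenience driver: per FOV, builds the cancer mask from the configured
#' cancer channel and the cancer-cell segmentations, the slide-background
#' mask from the summed channels, and the immune-aggregate mask from T/B
#' centroids, then derives the four compartments.
#'
#' @param ct a \linkS4class{CellTable}
#' @param images named list (by fov_id) of named channel-matrix lists
#' @param labelsList named list (by fov_id) of integer label matrices
#' @param cfg a \linkS4class{PanelConfig}
#' @param cancerChannel channel used for the cancer mask (default "ECAD";
#'   NULL to use cancer-cell segmentations alone)
#' @return named list of \linkS4class{CompartmentMaskSet}
#' @export
computeCompartments <- function(ct, images, labelsList, cfg,
                                cancerChannel = "ECAD") {
  out <- list()
  for (fov in fovIds(ct)) {
    cellsub <- fovCells(ct, fov)
    lab <- labelsList[[fov]]
    imgs <- images[[fov]]
    chan <- if (!is.null(cancerChannel)) imgs[[cancerChannel]] else NULL
    cancer <- buildCancerMask(chan, cellsub, lab, cfg)
    bg <- backgroundMask(imgs, cfg)
    ag <- immuneAggregateMask(cellsub, dim(lab), cfg)
    out[[fov]] <- deriveCompartments(cancer, background = bg,
      aggregates = ag, radius = panelParam(cfg, "border_radius"),
      fovId = fov)
  }
  out
}

#' Compartment areas in px^2
#' @param maskSet a \linkS4class{CompartmentMaskSet}
#' @return named numeric of the four compartment areas
#' @export
compartmentAreas <- function(maskSet) {
  vapply(maskSet@masks, sum, numeric(1))
}

setMethod("show", "CompartmentMaskSet", function(object) {
  a <- compartmentAreas(object)
  cat("CompartmentMaskSet", object@fovId, ":",
      paste(names(a), a, collapse = ", "), "\n")
})

#' Assign each cell to a compartment
#'
#' A cell takes the compartment containing the largest share of its pixels;
#' cells lying entirely in the aggregate or background mask are labelled
#' \code{"immune_agg"} / \code{"background"}. Ties break deterministically in
#' the fixed order cancer_core, cancer_border, stroma_border, stroma_core.
#'
#' @param cells data.frame of this FOV's cells
#' @param labels integer label matrix
#' @param maskSet a \linkS4class{CompartmentMaskSet}
#' @return character vector, one compartment per row of \code{cells}
#' @export
assignCells <- function(cells, labels, maskSet) {
  dims <- dim(labels)
  code <- matrix(0L, dims[1], dims[2])
  for (k in seq_along(COMPARTMENTS)) code[maskSet@masks[[k]]] <- k
  code[maskSet@aggregates] <- 5L
  code[maskSet@background] <- 6L
  inside <- labels > 0
  tab <- table(factor(labels[inside], levels = cells$cell_id),
               factor(code[inside], levels = 1:6))
  out <- character(nrow(cells))
  opts <- c(COMPARTMENTS, "immune_agg", "background")
  for (i in seq_len(nrow(cells))) {
    cnt <- as.numeric(tab[i, ])
    if (sum(cnt) == 0) {  # no rendered pixels: fall back to the centroid
      yx <- c(round(cells$centroid_y[i]) + 1, round(cells$centroid_x[i]) + 1)
      cnt[code[yx[1], yx[2]]] <- 1
    }
    out[i] <- if (sum(cnt[1:4]) > 0) opts[which.max(cnt[1:4])]
              else opts[4 + which.max(cnt[5:6])]
  }
  out
}

#' Compartment area features for one FOV
#'
#' Four area features plus the six unordered pairwise area ratios (numerator
#' earlier in the fixed compartment order). Ratios with a zero denominator
#' are missing with reason \code{undefined_ratio}.
#'
#' @param maskSet a \linkS4class{CompartmentMaskSet}
#' @return data.frame of feature rows (see \linkS4class{FeatureCatalog})
#' @export
compartmentAreaFeatures <- function(maskSet) {
  a <- compartmentAreas(maskSet)
  rows <- data.frame(
    fov_id = maskSet@fovId,
    feature_name = paste0("area__", names(a)),
    compartment = WHOLE_IMAGE, value = unname(a),
    category = "compartment_area", cell_types = "", markers = "",
    reason = NA_character_, stringsAsFactors = FALSE)
  for (i in 1:3) for (j in (i + 1):4) {
    nm <- paste0("area_ratio__", COMPARTMENTS[i], "__", COMPARTMENTS[j])
    den <- a[[COMPARTMENTS[j]]]
    rows <- rbind(rows, data.frame(
      fov_id = maskSet@fovId, feature_name = nm, compartment = WHOLE_IMAGE,
      value = if (den > 0) a[[COMPARTMENTS[i]]] / den else NA_real_,
      category = "compartment_area", cell_types = "", markers = "",
      reason = if (den > 0) NA_character_ else "undefined_ratio",
      stringsAsFactors = FALSE))
  }
  rows
}
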