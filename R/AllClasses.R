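#' @import methods
#' @importFrom stats median sd quantile rnorm runif rpois rbinom kmeans
#'   t.test cor complete.cases setNames aggregate dist p.adjust predict coef
#' @importFrom utils read.csv write.csv head
NULL

#' Recognised biopsy timepoints
#'
#' Sample timepoints used throughout the package: an archival primary tumor,
#' a pre-treatment baseline, an on-trial pre-nivolumab biopsy, and an
#' on-nivolumab biopsy.
#'
#' @export
TIMEPOINTS <- c("primary", "baseline", "pre_nivo", "on_nivo")

#' Compartment names, in fixed tie-break order
#'
#' The four tumor compartments derived from the cancer mask, ordered as used
#' for deterministic tie-breaking when a cell overlaps two compartments
#' equally, plus the whole-image pseudo-compartment.
#'
#' @export
COMPARTMENTS <- c("cancer_core", "cancer_border", "stroma_border", "stroma_core")

#' @rdname COMPARTMENTS
#' @export
WHOLE_IMAGE <- "whole_image"

#' Three-level cell-type hierarchy
#'
#' Maps every detailed cluster label to exactly one intermediate label and
#' every intermediate label to exactly one broad label. The number of labels
#' at each level is data-driven (a typical panel resolves ~33 detailed,
#' ~21 intermediate and 8 broad types), not hard-coded.
#'
#' @slot map data.frame with columns \code{detailed}, \code{intermediate},
#'   \code{broad}; one row per detailed label.
#' @export
setClass("ClusterHierarchy", representation(map = "data.frame"))

setValidity("ClusterHierarchy", function(object) {
  m <- object@map
  req <- c("detailed", "intermediate", "broad")
  if (!all(req %in% names(m)))
    return(paste("map must have columns", paste(req, collapse = ", ")))
  if (anyDuplicated(m$detailed))
    return("each detailed label must map to exactly one intermediate label")
  im <- unique(m[, c("intermediate", "broad")])
  if (anyDuplicated(im$intermediate))
    return("each intermediate label must map to exactly one broad label")
  if (any(is.na(m)) || any(m == ""))
    return("hierarchy labels must be non-missing and non-empty")
  TRUE
})

#' Per-cell table for a cohort of FOVs
#'
#' One record per segmented cell: identity (patient, timepoint, FOV, cell id
#' matching the label image), centroid in 0-based pixel coordinates, area,
#' cluster labels at the three hierarchy levels, per-channel mean intensities
#' and morphology metrics.
#'
#' @slot cells data.frame of per-cell records.
#' @slot hierarchy \linkS4class{ClusterHierarchy} resolving the labels.
#' @slot markers character, names of marker-intensity columns.
#' @slot morphology character, names of morphology columns (always contains
#'   \code{cell_area}).
#' @slot fovInfo data.frame with columns \code{fov_id}, \code{width},
#'   \code{height} (pixels) giving image bounds per FOV.
#' @export
setClass("CellTable", representation(
  cells = "data.frame", hierarchy = "ClusterHierarchy",
  markers = "character", morphology = "character", fovInfo = "data.frame"))

CELLTABLE_REQUIRED <- c("patient_id", "timepoint", "fov_id", "cell_id",
  "centroid_x", "centroid_y", "cell_area",
  "cluster_detailed", "cluster_intermediate", "cluster_broad")

setValidity("CellTable", function(object) {
  d <- object@cells
  miss <- setdiff(CELLTABLE_REQUIRED, names(d))
  if (length(miss))
    return(paste("missing required columns:", paste(miss, collapse = ", ")))
  if (nrow(d) == 0) return(TRUE)
  if (!all(d$timepoint %in% TIMEPOINTS))
    return(paste("unknown timepoint(s):",
                 paste(unique(setdiff(d$timepoint, TIMEPOINTS)), collapse = ", ")))
  if (any(d$cell_id < 1 | d$cell_id != round(d$cell_id)))
    return("cell_id must be positive integers")
  dup <- tapply(d$cell_id, d$fov_id, anyDuplicated)
  if (any(unlist(dup) > 0))
    return("cell_id must be unique within each FOV")
  mk <- intersect(object@markers, names(d))
  if (length(mk) < length(object@markers))
    return("marker columns missing from table")
  for (m in mk) if (any(d[[m]] < 0, na.rm = TRUE))
    return(paste("negative intensities in marker", m))
  h <- object@hierarchy@map
  bad <- setdiff(unique(d$cluster_detailed), h$detailed)
  if (length(bad))
    return(paste("cluster label(s) not in hierarchy:", paste(bad, collapse = ", ")))
  if (nrow(object@fovInfo)) {
    fi <- object@fovInfo
    idx <- match(d$fov_id, fi$fov_id)
    known <- !is.na(idx)
    oob <- known & (d$centroid_x < 0 | d$centroid_y < 0 |
                    d$centroid_x > fi$width[idx] - 1 | d$centroid_y > fi$height[idx] - 1)
    if (any(oob)) return("centroids outside FOV bounds")
  }
  TRUE
})

#' Panel configuration
#'
#' Declares which channels are lineage vs functional markers, per-marker
#' positivity thresholds, the morphology subset reported for cancer cells,
#' labels identifying cancer and aggregate-forming populations, ECM channels,
#' and the numeric analysis parameters (radii, minimum densities/counts,
#' tile sizes, cutoffs).
#'
#' @slot lineageMarkers,functionalMarkers character vectors of channel names.
#' @slot thresholds named numeric, positivity threshold per functional marker.
#' @slot cancerMorphology character, shape-metric columns reported for cancer
#'   cells only.
#' @slot cancerLabel broad-level label identifying cancer cells.
#' @slot aggregateLabels broad-level labels forming immune aggregates.
#' @slot ecmChannels the three extracellular-matrix channels.
#' @slot ecmThresholds named numeric, binarization threshold per ECM channel.
#' @slot params named list of numeric analysis parameters (see
#'   \code{\link{panelConfig}} for names and defaults).
#' @export
setClass("PanelConfig", representation(
  lineageMarkers = "character", functionalMarkers = "character",
  thresholds = "numeric", cancerMorphology = "character",
  cancerLabel = "character", aggregateLabels = "character",
  ecmChannels = "character", ecmThresholds = "numeric", params = "list"))

setValidity("PanelConfig", function(object) {
  if (length(object@thresholds) &&
      (is.null(names(object@thresholds)) || any(object@thresholds <= 0)))
    return("marker thresholds must be named and > 0")
  TRUE
})

#' Compartment masks for one FOV
#'
#' The four mutually exclusive tumor compartments plus the slide-background
#' and immune-aggregate masks. The six masks partition the FOV: every pixel
#' belongs to exactly one.
#'
#' @slot fovId FOV identifier.
#' @slot masks named list of four logical matrices (\code{cancer_core},
#'   \code{cancer_border}, \code{stroma_border}, \code{stroma_core}).
#' @slot background,aggregates logical matrices.
#' @export
setClass("CompartmentMaskSet", representation(
  fovId = "character", masks = "list",
  background = "matrix", aggregates = "matrix"))

setValidity("CompartmentMaskSet", function(object) {
  if (!identical(names(object@masks), COMPARTMENTS))
    return("masks must be named cancer_core, cancer_border, stroma_border, stroma_core")
  dims <- lapply(object@masks, dim)
  if (length(unique(dims)) != 1 ||
      !identical(dims[[1]], dim(object@background)) ||
      !identical(dims[[1]], dim(object@aggregates)))
    return("all masks must share one shape")
  total <- Reduce(`+`, lapply(object@masks, function(m) m * 1L)) +
    object@background + object@aggregates
  if (any(total != 1L))
    return("masks must partition the FOV (pairwise disjoint, full coverage)")
  TRUE
})

#' Long-format feature catalog
#'
#' One row per (FOV, feature, compartment) with the computed value or a
#' missingness reason, plus per-feature metadata: the broad category, the
#' cell types and markers involved.
#'
#' @slot values data.frame with columns \code{fov_id}, \code{feature_name},
#'   \code{compartment}, \code{value}, \code{category}, \code{cell_types},
#'   \code{markers}, \code{reason}.
#' @export
setClass("FeatureCatalog", representation(values = "data.frame"))

FEATURE_CATEGORIES <- c("density", "density_ratio", "density_proportion",
  "marker_positivity", "morphology", "diversity_abundance",
  "diversity_neighbor", "distance", "mixing", "neighborhood", "ecm",
  "compartment_area")

MISSING_REASONS <- c("below_min_cells", "below_min_density", "undefined_ratio",
  "zero_area", "no_cells", "no_target")

setValidity("FeatureCatalog", function(object) {
  v <- object@values
  req <- c("fov_id", "feature_name", "compartment", "value", "category",
           "cell_types", "markers", "reason")
  if (!all(req %in% names(v)))
    return(paste("values must have columns", paste(req, collapse = ", ")))
  if (nrow(v) == 0) return(TRUE)
  if (!all(v$category %in% FEATURE_CATEGORIES))
    return("unknown feature category")
  bad <- !is.na(v$value) & !is.finite(v$value)
  if (any(bad)) return("non-finite feature values must be missing with a reason")
  noreason <- is.na(v$value) & (is.na(v$reason) | v$reason == "")
  if (any(noreason)) return("missing values must carry a reason code")
  TRUE
})

#' Sample-by-feature matrix
#'
#' Harmonized cohort matrix: rows are (patient, timepoint) samples, columns
#' are retained feature/compartment combinations, values are z-scored means
#' over each sample's FOVs (NA where a feature could not be computed).
#'
#' @slot values numeric matrix, samples x features.
#' @slot sampleInfo data.frame with \code{patient_id}, \code{timepoint} per row.
#' @slot featureInfo data.frame with \code{column}, \code{feature_name},
#'   \code{compartment}, \code{category} per matrix column.
#' @export
setClass("FeatureMatrix", representation(
  values = "matrix", sampleInfo = "data.frame", featureInfo = "data.frame"))

setValidity("FeatureMatrix", function(object) {
  if (nrow(object@values) != nrow(object@sampleInfo))
    return("sampleInfo must have one row per matrix row")
  if (ncol(object@values) != nrow(object@featureInfo))
    return("featureInfo must have one row per matrix column")
  if (!identical(colnames(object@values), object@featureInfo$column))
    return("featureInfo$column must match matrix column names")
  TRUE
})
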