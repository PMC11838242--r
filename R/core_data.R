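#' Construct a cluster hierarchy
#'
#' @param map data.frame (or coercible) with columns \code{detailed},
#'   \code{intermediate}, \code{broad}.
#' @return A \linkS4class{ClusterHierarchy}.
#' @examples
#' h <- clusterHierarchy(data.frame(
#'   detailed = c("CD8T_PD1", "CD8T", "CD4T", "Tumor_ECAD"),
#'   intermediate = c("CD8T", "CD8T", "CD4T", "Tumor"),
#'   broad = c("T", "T", "T", "Cancer")))
#' resolveLabel(h, "CD8T_PD1", "broad")
#' @export
clusterHierarchy <- function(map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$detailed <- as.character(map$detailed)
  map$intermediate <- as.character(map$intermediate)
  map$broad <- as.character(map$broad)
  new("ClusterHierarchy", map = map[, c("detailed", "intermediate", "broad")])
}

#' Labels at one level of the hierarchy
#' @param x a \linkS4class{ClusterHierarchy}
#' @param level one of "detailed", "intermediate", "broad"
#' @export
hierarchyLevels <- function(x, level = c("detailed", "intermediate", "broad")) {
  level <- match.arg(level)
  unique(x@map[[level]])
}

#' Resolve a cluster label to a coarser level
#'
#' Resolution is functional: a given label always maps to the same parent.
#'
#' @param x a \linkS4class{ClusterHierarchy}
#' @param label character vector of detailed or intermediate labels
#' @param to target level
#' @export
resolveLabel <- function(x, label, to = c("broad", "intermediate")) {
  to <- match.arg(to)
  m <- x@map
  idx <- match(label, m$detailed)
  unresolved <- is.na(idx)
  out <- m[[to]][idx]
  if (any(unresolved)) {
    # allow resolving from the intermediate level directly
    im <- unique(m[, c("intermediate", "broad")])
    idx2 <- match(label[unresolved], im$intermediate)
    if (anyNA(idx2))
      stop("label(s) not in hierarchy: ",
           paste(unique(label[unresolved][is.na(idx2)]), collapse = ", "))
    out[unresolved] <- if (to == "broad") im$broad[idx2] else label[unresolved]
  }
  out
}

setMethod("show", "ClusterHierarchy", function(object) {
  m <- object@map
  cat("ClusterHierarchy:", nrow(m), "detailed /",
      length(unique(m$intermediate)), "intermediate /",
      length(unique(m$broad)), "broad labels\n")
})

#' Read a hierarchy from YAML/JSON
#'
#' The file holds a mapping broad -> intermediate -> [detailed, ...].
#' @param path file path
#' @export
readClusterHierarchy <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  rows <- list()
  for (broad in names(cfg)) {
    for (inter in names(cfg[[broad]])) {
      det <- unlist(cfg[[broad]][[inter]])
      rows[[length(rows) + 1L]] <- data.frame(
        detailed = as.character(det), intermediate = inter, broad = broad,
        stringsAsFactors = FALSE)
    }
  }
  clusterHierarchy(do.call(rbind, rows))
}

#' Construct a CellTable
#'
#' Missing \code{cluster_intermediate}/\code{cluster_broad} columns are filled
#' by resolving \code{cluster_detailed} through the hierarchy.
#'
#' @param cells data.frame of per-cell records (see \linkS4class{CellTable}).
#' @param hierarchy a \linkS4class{ClusterHierarchy}.
#' @param markers names of the marker-intensity columns; default: all numeric
#'   columns not otherwise claimed.
#' @param morphology names of the morphology columns (cell_area always added).
#' @param fovInfo optional data.frame \code{fov_id}, \code{width}, \code{height}.
#' @return A validated \linkS4class{CellTable}.
#' @export
cellTable <- function(cells, hierarchy, markers = NULL,
                      morphology = character(), fovInfo = NULL) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (!"cluster_intermediate" %in% names(cells) && "cluster_detailed" %in% names(cells))
    cells$cluster_intermediate <- resolveLabel(hierarchy, cells$cluster_detailed,
                                               "intermediate")
  if (!"cluster_broad" %in% names(cells) && "cluster_detailed" %in% names(cells))
    cells$cluster_broad <- resolveLabel(hierarchy, cells$cluster_detailed, "broad")
  if (is.null(markers)) {
    claimed <- c(CELLTABLE_REQUIRED, morphology)
    markers <- names(cells)[vapply(cells, is.numeric, TRUE) & !names(cells) %in% claimed]
  }
  morphology <- union("cell_area", morphology)
  if (is.null(fovInfo))
    fovInfo <- data.frame(fov_id = character(), width = numeric(),
                          height = numeric(), stringsAsFactors = FALSE)
  new("CellTable", cells = cells, hierarchy = hierarchy,
      markers = as.character(markers), morphology = morphology,
      fovInfo = as.data.frame(fovInfo, stringsAsFactors = FALSE))
}

#' @rdname cellTable
#' @param x a CellTable
#' @export
cells <- function(x) x@cells

#' @rdname cellTable
#' @export
markerNames <- function(x) x@markers

#' @rdname cellTable
#' @export
hierarchy <- function(x) x@hierarchy

#' @rdname cellTable
#' @export
fovIds <- function(x) unique(x@cells$fov_id)

#' Subset a CellTable to one FOV
#' @param x a CellTable
#' @param fov fov_id
#' @export
fovCells <- function(x, fov) x@cells[x@cells$fov_id == fov, , drop = FALSE]

setMethod("show", "CellTable", function(object) {
  d <- object@cells
  cat("CellTable:", nrow(d), "cells,", length(unique(d$fov_id)), "FOVs,",
      length(unique(d$patient_id)), "patients\n")
  cat("  markers:", length(object@markers),
      " morphology:", length(object@morphology), "\n")
})

#' Load a cell table from CSV
#'
#' Delimited text, UTF-8, header row; one file may hold many FOVs.
#' Unknown cluster labels raise a mapping error naming the label; missing
#' required columns raise a schema error.
#'
#' @inheritParams cellTable
#' @param path CSV path
#' @export
loadCellTable <- function(path, hierarchy, markers = NULL,
                          morphology = character(), fovInfo = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  base <- setdiff(CELLTABLE_REQUIRED, c("cluster_intermediate", "cluster_broad"))
  miss <- setdiff(base, names(d))
  if (length(miss))
    stop("cell table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  cellTable(d, hierarchy, markers = markers, morphology = morphology,
            fovInfo = fovInfo)
}

#' Write a cell table to CSV
#' @param x a CellTable
#' @param path output CSV path
#' @export
writeCellTable <- function(x, path) {
  write.csv(x@cells, path, row.names = FALSE)
  invisible(path)
}

#' Check a FOV's cells against its label image
#'
#' Report-only consistency check: the set of positive labels in the image must
#' equal the set of cell ids, and every centroid must lie inside the image.
#'
#' @param cells data.frame of cells for one FOV (or a CellTable holding one FOV)
#' @param labels integer label matrix (0 = background)
#' @return character vector of violations (empty when consistent)
#' @export
validateFov <- function(cells, labels) {
  if (is(cells, "CellTable")) cells <- cells@cells
  viol <- character()
  ids <- sort(unique(cells$cell_id))
  lab <- sort(setdiff(unique(as.integer(labels)), 0L))
  orphan <- setdiff(lab, ids)
  if (length(orphan))
    viol <- c(viol, paste0("orphan label ", orphan, " in label image"))
  absent <- setdiff(ids, lab)
  if (length(absent))
    viol <- c(viol, paste0("cell ", absent, " missing from label image"))
  w <- ncol(labels); h <- nrow(labels)
  oob <- cells$centroid_x < 0 | cells$centroid_x > w - 1 |
         cells$centroid_y < 0 | cells$centroid_y > h - 1
  if (any(oob))
    viol <- c(viol, paste0("cell ", cells$cell_id[oob],
                           " centroid out of bounds"))
  viol
}

# ---- image IO -------------------------------------------------------------

CHANNEL_SCALE <- 65535  # counts are stored as float32 fractions of this

#' Read / write channel and label images
#'
#' Channel images are single-channel 32-bit float TIFFs holding counts per
#' pixel divided by a fixed scale of 65535 (float storage is exact to ~1e-7
#' relative; counts must stay below the scale). Label images are unsigned
#' 16-bit integer TIFFs (0 = background), round-tripped bit-exactly.
#'
#' @param path TIFF path
#' @return numeric (channel) or integer (label) matrix, rows = y, cols = x
#' @export
readChannelImage <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * CHANNEL_SCALE
}

#' @rdname readChannelImage
#' @param img numeric matrix of non-negative values
#' @export
writeChannelImage <- function(img, path) {
  stopifnot(all(is.finite(img)), all(img >= 0), max(img) < CHANNEL_SCALE)
  tiff::writeTIFF(img / CHANNEL_SCALE, path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname readChannelImage
#' @export
readLabelImage <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

#' @rdname readChannelImage
#' @param labels integer matrix, 0 = background, positive = cell ids
#' @export
writeLabelImage <- function(labels, path) {
  stopifnot(all(labels >= 0), max(labels) < 65536)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

# ---- panel configuration --------------------------------------------------

.defaultParams <- function() list(
  border_radius = 50,          # px, compartment erosion/dilation radius
  neighbor_radius = 50,        # px, neighbor/mixing/diversity radius
  min_density = 5e-7,          # cells/px^2 floor for density ratios
  min_cells = 5,               # per-FOV minimum for marker frequencies
  prevalence_floor = 0.05,     # cohort-wide marker admission fraction
  tile_size = 256,             # px, ECM tile edge
  ecm_min_frac = 0.10,         # minimum ECM-mask fraction per tile
  n_neighborhoods = 12,        # k for cellular-neighborhood k-means
  kmeans_seed = 42,
  smooth_sigma = 10,           # px, cancer-mask / background smoothing
  cancer_threshold = NA_real_, # NA = Otsu on the smoothed cancer channel
  background_threshold = 0.1,  # on smoothed total signal
  hole_fill = 2500,            # px^2, holes below this are filled
  min_component = 10000,       # px^2, cancer components below this dropped
  aggregate_sigma = 25,        # px, KDE bandwidth for immune aggregates
  aggregate_density = 8e-4,    # cells/px^2 KDE threshold
  aggregate_min_area = 5000,   # px^2
  ecm_smooth_sigma = 2,        # px, ECM channel smoothing
  distance_corr_cutoff = 0.7,  # |r| above which distance features are dropped
  redundancy_cutoff = 0.8,     # compartment-vs-whole-image correlation cutoff
  super_groups = list())       # named broad-type groups for diversity

#' Construct a panel configuration
#'
#' @param lineageMarkers,functionalMarkers channel names.
#' @param thresholds named numeric positivity thresholds (> 0), one per
#'   functional marker, applied identically across all cell types.
#' @param cancerMorphology shape-metric columns reported for cancer cells.
#' @param cancerLabel,aggregateLabels broad-level labels for cancer cells and
#'   for the aggregate-forming (T/B) populations.
#' @param ecmChannels,ecmThresholds extracellular-matrix channels and their
#'   binarization thresholds.
#' @param params named list overriding entries of the default analysis
#'   parameters; see Details.
#' @details Default parameters: border_radius 50 px, neighbor_radius 50 px,
#'   min_density 5e-7 cells/px^2, min_cells 5, prevalence_floor 0.05,
#'   tile_size 256 px, ecm_min_frac 0.10, n_neighborhoods 12,
#'   redundancy_cutoff 0.8, distance_corr_cutoff 0.7, plus mask-construction
#'   parameters (smooth_sigma, hole_fill, min_component, aggregate_*).
#' @export
panelConfig <- function(lineageMarkers = character(),
                        functionalMarkers = character(),
                        thresholds = numeric(),
                        cancerMorphology = character(),
                        cancerLabel = "Cancer",
                        aggregateLabels = c("T", "B"),
                        ecmChannels = c("Collagen1", "Fibronectin", "FAP"),
                        ecmThresholds = numeric(),
                        params = list()) {
  p <- .defaultParams()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(params)] <- params
  new("PanelConfig", lineageMarkers = lineageMarkers,
      functionalMarkers = functionalMarkers, thresholds = thresholds,
      cancerMorphology = cancerMorphology, cancerLabel = cancerLabel,
      aggregateLabels = aggregateLabels, ecmChannels = ecmChannels,
      ecmThresholds = ecmThresholds, params = p)
}

#' Retrieve one analysis parameter
#' @param cfg a \linkS4class{PanelConfig}
#' @param name parameter name
#' @export
panelParam <- function(cfg, name) {
  if (!name %in% names(cfg@params)) stop("unknown parameter: ", name)
  cfg@params[[name]]
}

#' Read a panel configuration from YAML/JSON
#' @param path file path; top-level keys mirror the \code{\link{panelConfig}}
#'   arguments
#' @export
readPanelConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  args <- list()
  for (nm in c("lineageMarkers", "functionalMarkers", "cancerMorphology",
               "cancerLabel", "aggregateLabels", "ecmChannels"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- unlist(cfg[[nm]])
  for (nm in c("thresholds", "ecmThresholds"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- unlist(cfg[[nm]])
  if (!is.null(cfg$params)) args$params <- cfg$params
  do.call(panelConfig, args)
}

#' Check a panel configuration against a cell table
#'
#' Every configured marker must exist as a column of the table.
#' @param cfg a \linkS4class{PanelConfig}
#' @param ct a \linkS4class{CellTable}
#' @export
validatePanel <- function(cfg, ct) {
  need <- unique(c(cfg@functionalMarkers, names(cfg@thresholds)))
  miss <- setdiff(need, names(ct@cells))
  if (length(miss))
    stop("configured marker(s) absent from cell table: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

setMethod("show", "PanelConfig", function(object) {
  cat("PanelConfig:", length(object@lineageMarkers), "lineage,",
      length(object@functionalMarkers), "functional markers;",
      "cancer label:", object@cancerLabel, "\n")
})
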