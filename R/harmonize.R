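# Cohort harmonization: long catalog -> wide FOV matrix -> redundancy filter
# -> z-score -> per-sample (patient x timepoint) aggregation. The pipeline
# order is fixed: features are z-scored at the FOV level first and FOVs of a
# sample are averaged afterwards (a sample-level z-scoring switch is
# provided). Re-running any step on its own output is a no-op.

.columnKey <- function(feature, compartment) paste0(feature, "::", compartment)

# long catalog -> wide FOV x column matrix plus column metadata
.catalogWide <- function(catalog) {
  v <- catalog@values
  col <- .columnKey(v$feature_name, v$compartment)
  fovs <- unique(v$fov_id)
  colsU <- unique(col)
  m <- matrix(NA_real_, length(fovs), length(colsU),
              dimnames = list(fovs, colsU))
  m[cbind(match(v$fov_id, fovs), match(col, colsU))] <- v$value
  meta <- v[!duplicated(col),
            c("feature_name", "compartment", "category", "cell_types",
              "markers")]
  meta$column <- colsU
  list(values = m, meta = meta[, c("column", "feature_name", "compartment",
                                   "category", "cell_types", "markers")])
}

#' Drop compartment features redundant with their whole-image twin
#'
#' For every feature computed both per compartment and image-wide, the
#' compartment rows are removed when the Pearson correlation (across FOVs,
#' pairwise-complete observations) with the whole-image values exceeds
#' \code{cutoff}. Whole-image features are always kept; features with fewer
#' than 3 complete pairs are kept with a warning.
#'
#' @param catalog a \linkS4class{FeatureCatalog}
#' @param cutoff correlation cutoff (default 0.8)
#' @export
filterCompartmentRedundancy <- function(catalog, cutoff = 0.8) {
  v <- catalog@values
  drop <- rep(FALSE, nrow(v))
  isComp <- v$compartment != WHOLE_IMAGE
  for (nm in unique(v$feature_name[isComp])) {
    wi <- v[v$feature_name == nm & v$compartment == WHOLE_IMAGE,
            c("fov_id", "value")]
    if (!nrow(wi)) next
    for (cp in unique(v$compartment[isComp & v$feature_name == nm])) {
      sel <- v$feature_name == nm & v$compartment == cp
      m <- merge(v[sel, c("fov_id", "value")], wi, by = "fov_id")
      m <- m[complete.cases(m), ]
      if (nrow(m) < 3) {
        warning("fewer than 3 complete pairs for ", nm, " in ", cp,
                "; feature kept")
        next
      }
      if (sd(m$value.x) == 0 || sd(m$value.y) == 0) next
      if (cor(m$value.x, m$value.y) > cutoff) drop <- drop | sel
    }
  }
  new("FeatureCatalog", values = v[!drop, , drop = FALSE])
}

#' Z-score catalog features across FOVs
#'
#' (x - mean) / SD per (feature, compartment) column over non-missing FOV
#' values, with the sample (n-1) SD. Columns with fewer than 2 non-missing
#' values or zero variance are dropped with a warning.
#'
#' @param catalog a \linkS4class{FeatureCatalog}
#' @export
zscoreFeatures <- function(catalog) {
  v <- catalog@values
  key <- .columnKey(v$feature_name, v$compartment)
  keep <- rep(TRUE, nrow(v))
  for (k in unique(key)) {
    sel <- key == k
    x <- v$value[sel]
    ok <- !is.na(x)
    if (sum(ok) < 2 || sd(x[ok]) == 0) {
      warning("dropping constant or near-empty feature ", k)
      keep[sel] <- FALSE
      next
    }
    v$value[sel] <- (x - mean(x[ok])) / sd(x[ok])
  }
  new("FeatureCatalog", values = v[keep, , drop = FALSE])
}

#' Aggregate FOV-level features to samples
#'
#' Per (patient, timepoint), the mean over that sample's FOVs of each
#' feature, ignoring missing FOVs.
#'
#' @param catalog a \linkS4class{FeatureCatalog}
#' @param fovMeta data.frame with columns \code{fov_id}, \code{patient_id},
#'   \code{timepoint} (the mapping must cover every FOV)
#' @return a \linkS4class{FeatureMatrix}
#' @export
aggregateToSample <- function(catalog, fovMeta) {
  w <- .catalogWide(catalog)
  fovs <- rownames(w$values)
  idx <- match(fovs, fovMeta$fov_id)
  if (anyNA(idx))
    stop("fovMeta does not cover FOV(s): ",
         paste(fovs[is.na(idx)], collapse = ", "))
  sampleKey <- paste(fovMeta$patient_id[idx], fovMeta$timepoint[idx],
                     sep = "||")
  samples <- unique(sampleKey)
  out <- matrix(NA_real_, length(samples), ncol(w$values),
                dimnames = list(samples, colnames(w$values)))
  for (s in samples) {
    rows <- w$values[sampleKey == s, , drop = FALSE]
    mm <- colMeans(rows, na.rm = TRUE)
    mm[!is.finite(mm)] <- NA_real_
    out[s, ] <- mm
  }
  parts <- strsplit(samples, "||", fixed = TRUE)
  si <- data.frame(patient_id = vapply(parts, `[`, "", 1),
                   timepoint = vapply(parts, `[`, "", 2),
                   stringsAsFactors = FALSE)
  fi <- w$meta
  rownames(fi) <- NULL
  new("FeatureMatrix", values = out, sampleInfo = si, featureInfo = fi)
}

#' Harmonize a feature catalog into a cohort matrix
#'
#' Fixed pipeline: compartment-redundancy filter, z-scoring of FOV-level
#' values, then FOV-to-sample averaging (or z-scoring after aggregation with
#' \code{zscoreLevel = "sample"}).
#'
#' @param catalog a \linkS4class{FeatureCatalog}
#' @param fovMeta data.frame \code{fov_id}, \code{patient_id}, \code{timepoint}
#' @param redundancyCutoff compartment/whole-image correlation cutoff
#' @param zscoreLevel "fov" (default), "sample", or "none"
#' @return a \linkS4class{FeatureMatrix}
#' @export
buildFeatureMatrix <- function(catalog, fovMeta, redundancyCutoff = 0.8,
                               zscoreLevel = c("fov", "sample", "none")) {
  zscoreLevel <- match.arg(zscoreLevel)
  catalog <- filterCompartmentRedundancy(catalog, cutoff = redundancyCutoff)
  if (zscoreLevel == "fov") catalog <- zscoreFeatures(catalog)
  fm <- aggregateToSample(catalog, fovMeta)
  if (zscoreLevel == "sample") {
    v <- fm@values
    keep <- rep(TRUE, ncol(v))
    for (j in seq_len(ncol(v))) {
      x <- v[, j]; ok <- !is.na(x)
      if (sum(ok) < 2 || sd(x[ok]) == 0) { keep[j] <- FALSE; next }
      v[, j] <- (x - mean(x[ok])) / sd(x[ok])
    }
    fm <- new("FeatureMatrix", values = v[, keep, drop = FALSE],
              sampleInfo = fm@sampleInfo,
              featureInfo = fm@featureInfo[keep, , drop = FALSE])
  }
  fm
}

#' @rdname buildFeatureMatrix
#' @param x a FeatureMatrix
#' @export
matrixValues <- function(x) x@values

#' @rdname buildFeatureMatrix
#' @export
sampleInfo <- function(x) x@sampleInfo

#' @rdname buildFeatureMatrix
#' @export
featureInfo <- function(x) x@featureInfo

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "features (",
      round(100 * mean(is.na(object@values)), 1), "% missing )\n")
})

#' Write / read a feature matrix as CSV
#'
#' The matrix CSV has patient_id and timepoint as leading columns; feature
#' metadata goes to a companion CSV.
#'
#' @param fm a \linkS4class{FeatureMatrix}
#' @param path matrix CSV path
#' @param metaPath optional metadata CSV path
#' @export
writeFeatureMatrix <- function(fm, path, metaPath = NULL) {
  d <- cbind(fm@sampleInfo, as.data.frame(fm@values, check.names = FALSE))
  write.csv(d, path, row.names = FALSE)
  if (!is.null(metaPath)) write.csv(fm@featureInfo, metaPath, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path, metaPath = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  si <- d[, c("patient_id", "timepoint")]
  si$patient_id <- as.character(si$patient_id)
  v <- as.matrix(d[, setdiff(names(d), c("patient_id", "timepoint")),
                   drop = FALSE])
  rownames(v) <- paste(si$patient_id, si$timepoint, sep = "||")
  fi <- if (!is.null(metaPath))
    read.csv(metaPath, stringsAsFactors = FALSE, check.names = FALSE)
  else data.frame(column = colnames(v),
                  feature_name = sub("::.*$", "", colnames(v)),
                  compartment = sub("^.*::", "", colnames(v)),
                  category = NA_character_, cell_types = "", markers = "",
                  stringsAsFactors = FALSE)
  new("FeatureMatrix", values = v, sampleInfo = si, featureInfo = fi)
}
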