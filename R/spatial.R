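# Spatial primitives shared by the diversity, distance, mixing and
# neighborhood features. All relations use centroid Euclidean distance with a
# strict "< radius" rule, and the index cell is never its own neighbor.

# logical adjacency rows for a block of index cells against all cells
.neighborBlock <- function(xy, rows, radius) {
  d2 <- crossDist2(xy[rows, , drop = FALSE], xy)
  adj <- d2 < radius^2
  adj[cbind(seq_along(rows), rows)] <- FALSE
  adj
}

#' Per-cell neighbor type counts
#'
#' For each cell, the number of cells of each type with centroid strictly
#' within \code{radius} pixels, excluding the cell itself. The relation is
#' symmetric: A counts B iff B counts A.
#'
#' @param cells data.frame of one FOV's cells (\code{centroid_x},
#'   \code{centroid_y} required)
#' @param radius neighborhood radius in px (default 50)
#' @param types character vector of the cell types of each row (e.g. a
#'   cluster column of \code{cells})
#' @param levels full set of type labels defining the count columns
#' @param block rows per chunk of the distance computation
#' @return integer matrix, cells x levels
#' @export
neighborCounts <- function(cells, types, radius = 50,
                           levels = sort(unique(types)), block = 1024L) {
  n <- nrow(cells)
  out <- matrix(0L, n, length(levels), dimnames = list(NULL, levels))
  if (n == 0) return(out)
  xy <- cbind(cells$centroid_x, cells$centroid_y)
  ind <- outer(types, levels, "==") * 1L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    out[rows, ] <- .neighborBlock(xy, rows, radius) %*% ind
  }
  storage.mode(out) <- "integer"
  out
}

#' Mean nearest-neighbor distance between two cell types
#'
#' For every cell of \code{sourceType}, the centroid distance to the nearest
#' cell of \code{targetType}, averaged over source cells. Defined only for
#' distinct types; NA when either population is absent.
#'
#' @param cells data.frame of one FOV's cells
#' @param types type label per row
#' @param sourceType,targetType distinct type labels
#' @export
nearestDistance <- function(cells, types, sourceType, targetType) {
  if (sourceType == targetType)
    stop("nearest distances are defined between distinct types")
  src <- which(types == sourceType)
  tgt <- which(types == targetType)
  if (!length(src) || !length(tgt)) return(NA_real_)
  xy <- cbind(cells$centroid_x, cells$centroid_y)
  d2 <- crossDist2(xy[src, , drop = FALSE], xy[tgt, , drop = FALSE])
  mean(sqrt(apply(d2, 1, min)))
}

#' Mixing score between two cell populations
#'
#' Counts, over all cells of the two types, the neighbors of the opposite
#' type (heterotypic) and of the same type (homotypic) within \code{radius}.
#' The pooled score (default) is total heterotypic / total homotypic link
#' counts; the \code{"percell"} mode averages the per-cell ratio over cells
#' with at least one homotypic neighbor. The score is symmetric in the two
#' types, and NA when no homotypic links exist (or, trivially, when one of
#' the populations is absent).
#'
#' @param cells data.frame of one FOV's cells
#' @param types type label per row
#' @param typeA,typeB the unordered pair
#' @param radius px (default 50)
#' @param mode "pooled" or "percell"
#' @export
mixingScore <- function(cells, types, typeA, typeB, radius = 50,
                        mode = c("pooled", "percell")) {
  mode <- match.arg(mode)
  sel <- types %in% c(typeA, typeB)
  if (!any(types == typeA) || !any(types == typeB)) return(NA_real_)
  sub <- cells[sel, , drop = FALSE]
  tsub <- types[sel]
  cnt <- neighborCounts(sub, tsub, radius = radius, levels = c(typeA, typeB))
  same <- ifelse(tsub == typeA, cnt[, typeA], cnt[, typeB])
  other <- ifelse(tsub == typeA, cnt[, typeB], cnt[, typeA])
  if (mode == "pooled") {
    if (sum(same) == 0) return(NA_real_)
    sum(other) / sum(same)
  } else {
    ok <- same > 0
    if (!any(ok)) return(NA_real_)
    mean(other[ok] / same[ok])
  }
}
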