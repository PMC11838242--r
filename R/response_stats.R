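# Univariate response associations: per feature and timepoint, a Welch
# two-sample t-test p-value and the responder-minus-non-responder median
# difference; a composite 0-1 importance score aggregating the p-value rank
# and the effect-size rank; paired-timepoint evolution features; and a
# patient-level label-shuffle robustness check.

# samples of one timepoint with their labels attached
.timepointData <- function(fm, labels, timepoint) {
  sel <- fm@sampleInfo$timepoint == timepoint
  if (!any(sel)) stop("no samples at timepoint ", timepoint)
  idx <- match(fm@sampleInfo$patient_id[sel], labels$patient_id)
  if (anyNA(idx))
    stop("missing response label(s) for patient(s): ",
         paste(fm@sampleInfo$patient_id[sel][is.na(idx)], collapse = ", "))
  list(x = fm@values[sel, , drop = FALSE],
       y = as.integer(labels$response[idx]),
       patients = fm@sampleInfo$patient_id[sel])
}

#' Univariate feature-response associations at one timepoint
#'
#' For each feature: a Welch (unequal-variance) two-sample t-test p-value
#' between responders and non-responders, and the difference in medians
#' (responders minus non-responders). Features with fewer than 2 non-missing
#' values in either class are skipped.
#'
#' @param fm a \linkS4class{FeatureMatrix}
#' @param labels data.frame with \code{patient_id} and binary \code{response}
#'   (1 = responder)
#' @param timepoint timepoint to analyse
#' @return data.frame: feature_name, timepoint, p_value, med_diff
#' @export
univariateAssociations <- function(fm, labels, timepoint) {
  td <- .timepointData(fm, labels, timepoint)
  if (length(unique(td$y)) < 2)
    stop("analysis error: a single response class at timepoint ", timepoint)
  out <- lapply(colnames(td$x), function(cn) {
    x <- td$x[, cn]
    a <- x[td$y == 1]; b <- x[td$y == 0]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2 ||
        (sd(a) == 0 && sd(b) == 0)) return(NULL)
    tt <- t.test(a, b, var.equal = FALSE)
    data.frame(feature_name = cn, timepoint = timepoint,
               p_value = tt$p.value, med_diff = median(a) - median(b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Composite importance scores by rank aggregation
#'
#' P-values are ranked ascending (smallest = best) and absolute median
#' shifts descending (largest = best), with average ranks for ties; the two
#' ranks are averaged and rescaled so the best average rank scores 1 and the
#' worst 0. Records from all timepoints are ranked jointly by default,
#' producing a single set of scores across timepoints; \code{perTimepoint}
#' ranks within each timepoint instead.
#'
#' @param records rows from \code{\link{univariateAssociations}} (possibly
#'   several timepoints, row-bound)
#' @param perTimepoint rank within timepoint rather than jointly
#' @param fdr add a Benjamini-Hochberg adjusted p-value column
#' @return records with p_rank, effect_rank, avg_rank, importance_score
#' @export
importanceScores <- function(records, perTimepoint = FALSE, fdr = FALSE) {
  score <- function(d) {
    d$p_rank <- rank(d$p_value)
    d$effect_rank <- rank(-abs(d$med_diff))
    d$avg_rank <- (d$p_rank + d$effect_rank) / 2
    n <- nrow(d)
    # rescaled so an average rank of 1 (best on both criteria) scores 1 and
    # an average rank of n (worst on both) scores 0
    d$importance_score <- if (n > 1) 1 - (d$avg_rank - 1) / (n - 1) else 1
    d
  }
  out <- if (perTimepoint)
    do.call(rbind, lapply(split(records, records$timepoint), score))
  else score(records)
  if (fdr) out$p_fdr <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[order(-out$importance_score), ]
}

#' Default paired-timepoint comparisons
#' @export
EVOLUTION_PAIRS <- list(c("primary", "baseline"), c("baseline", "pre_nivo"),
                        c("baseline", "on_nivo"), c("pre_nivo", "on_nivo"))

#' Evolution features across paired timepoints
#'
#' For each configured (earlier, later) timepoint pair and each patient with
#' both samples, later-minus-earlier change per feature, emitted as a new
#' \linkS4class{FeatureMatrix} whose timepoints are named
#' "earlier__to__later". The result feeds \code{\link{univariateAssociations}}
#' unchanged.
#'
#' @param fm a \linkS4class{FeatureMatrix}
#' @param pairs list of c(earlier, later) timepoint pairs
#' @export
evolutionFeatures <- function(fm, pairs = EVOLUTION_PAIRS) {
  si <- fm@sampleInfo
  rowsV <- list(); rowsS <- list()
  for (pr in pairs) {
    e <- which(si$timepoint == pr[1]); l <- which(si$timepoint == pr[2])
    shared <- intersect(si$patient_id[e], si$patient_id[l])
    if (!length(shared)) next
    ei <- e[match(shared, si$patient_id[e])]
    li <- l[match(shared, si$patient_id[l])]
    delta <- fm@values[li, , drop = FALSE] - fm@values[ei, , drop = FALSE]
    tp <- paste0(pr[1], "__to__", pr[2])
    rownames(delta) <- paste(shared, tp, sep = "||")
    rowsV[[tp]] <- delta
    rowsS[[tp]] <- data.frame(patient_id = shared, timepoint = tp,
                              stringsAsFactors = FALSE)
  }
  if (!length(rowsV)) stop("no patient has both timepoints of any pair")
  new("FeatureMatrix", values = do.call(rbind, rowsV),
      sampleInfo = do.call(rbind, rowsS), featureInfo = fm@featureInfo)
}

#' Label-shuffle robustness of the importance ranking
#'
#' Outcome labels are permuted at the patient level (each patient keeps one
#' shuffled label across timepoints) and the full univariate + importance
#' analysis is rerun per permutation. The mean p-value and the mean absolute
#' median shift of the top-\code{k} features are recorded per permutation
#' and compared with the observed values.
#'
#' @param fm a \linkS4class{FeatureMatrix}
#' @param labels data.frame \code{patient_id}, \code{response}
#' @param timepoints timepoints to pool (default: all present)
#' @param k top-feature count (default 100)
#' @param nPerm number of permutations (default 100)
#' @param seed RNG seed
#' @return list: observed top-k mean p / mean |med_diff|, per-permutation
#'   values, and exceedance fractions (how often a shuffle looks at least as
#'   extreme as the observed data)
#' @export
permutationRobustness <- function(fm, labels, timepoints = NULL, k = 100,
                                  nPerm = 100, seed = 1) {
  if (is.null(timepoints)) timepoints <- unique(fm@sampleInfo$timepoint)
  runOnce <- function(lab) {
    rec <- do.call(rbind, lapply(timepoints, function(tp)
      univariateAssociations(fm, lab, tp)))
    sc <- importanceScores(rec)
    top <- head(sc, min(k, nrow(sc)))
    c(mean_p = mean(top$p_value), mean_med = mean(abs(top$med_diff)))
  }
  obs <- runOnce(labels)
  set.seed(seed)
  perm <- t(vapply(seq_len(nPerm), function(i) {
    lab <- labels
    lab$response <- sample(lab$response)
    runOnce(lab)
  }, c(mean_p = 0, mean_med = 0)))
  structure(list(
    n_permutations = nPerm, k = k, observed = obs,
    perm_mean_p = perm[, "mean_p"], perm_mean_med = perm[, "mean_med"],
    exceed_p = mean(perm[, "mean_p"] <= obs[["mean_p"]]),
    exceed_med = mean(perm[, "mean_med"] >= obs[["mean_med"]])),
    class = "PermutationReport")
}

#' @method print PermutationReport
#' @export
print.PermutationReport <- function(x, ...) {
  cat("PermutationReport:", x$n_permutations, "patient-level label shuffles,",
      "top", x$k, "features\n")
  cat(sprintf("  observed mean p %.4g (shuffles as small: %.2f)\n",
              x$observed[["mean_p"]], x$exceed_p))
  cat(sprintf("  observed mean |med shift| %.4g (shuffles as large: %.2f)\n",
              x$observed[["mean_med"]], x$exceed_med))
  invisible(x)
}
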