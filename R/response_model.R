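# Multivariate response prediction: L1-penalized logistic regression with
# nested stratified cross-validation. The inner stratified CV selects the
# penalty by AUROC; outer stratified folds give held-out AUROCs; the whole
# scheme is replicated over seeds. Imputation (training-fold means) and
# standardization (training-fold mean/SD) are always estimated on training
# data only and applied to the held-out part, so no information leaks.

# training-estimated imputation + standardization, applied to both parts
.fitScaler <- function(xtr) {
  mu <- colMeans(xtr, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  xtr <- sweep(xtr, 2, mu, function(x, m) ifelse(is.na(x), m, x))
  ctr <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(impute = mu, center = ctr, scale = sdv)
}

.applyScaler <- function(x, sc) {
  x <- sweep(x, 2, sc$impute, function(v, m) ifelse(is.na(v), m, v))
  scale(x, center = sc$center, scale = sc$scale)
}

# stratified-CV lasso on (x, y): returns chosen lambda and the glmnet fit
.cvLasso <- function(x, y, folds, nLambda) {
  foldid <- stratifiedFolds(y, folds)
  cv <- suppressWarnings(glmnet::cv.glmnet(
    x, y, family = "binomial", alpha = 1, type.measure = "auc",
    foldid = foldid, nlambda = nLambda, standardize = FALSE))
  list(lambda = cv$lambda.min, fit = cv$glmnet.fit)
}

#' Fit the response classifier with nested stratified CV
#'
#' For each seed: outer stratified folds are held out in turn; on each
#' training part, an inner stratified CV over a log-spaced penalty grid
#' picks the L1 penalty by AUROC, the model is refit at that penalty, and
#' the held-out fold is scored. The per-seed AUROC is the mean over outer
#' folds (\code{pooled = TRUE} concatenates held-out predictions instead).
#' Per seed, a final model is also fitted on all samples (penalty again by
#' stratified CV) to provide the coefficient vector used for feature
#' selection.
#'
#' @param fm a \linkS4class{FeatureMatrix}
#' @param labels data.frame \code{patient_id}, \code{response}
#' @param timepoint timepoint to model
#' @param baseSeed first replicate seed; replicates use consecutive integers
#' @param nSeeds number of replicates (default 10)
#' @param folds stratified folds, outer and inner (default 3)
#' @param nLambda penalty-grid size (default 50)
#' @param pooled pool held-out predictions across folds before the AUROC
#' @return a \code{ModelReport} list: per-seed fold AUROCs, mean/SD AUROC,
#'   chosen penalties, and the feature-by-seed coefficient matrix
#' @export
fitResponseModel <- function(fm, labels, timepoint, baseSeed = 1,
                             nSeeds = 10, folds = 3, nLambda = 50,
                             pooled = FALSE) {
  td <- .timepointData(fm, labels, timepoint)
  keep <- colSums(!is.na(td$x)) > 0
  x <- td$x[, keep, drop = FALSE]
  y <- td$y
  if (length(unique(y)) < 2) stop("single response class at ", timepoint)
  seeds <- baseSeed + seq_len(nSeeds) - 1L
  coefMat <- matrix(0, ncol(x), nSeeds,
                    dimnames = list(colnames(x), paste0("seed", seeds)))
  aurocSeed <- numeric(nSeeds)
  foldAuroc <- vector("list", nSeeds)
  lambdas <- numeric(nSeeds)
  for (si in seq_along(seeds)) {
    set.seed(seeds[si])
    fold <- stratifiedFolds(y, folds)
    fa <- numeric(folds)
    preds <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      sc <- .fitScaler(x[tr, , drop = FALSE])
      xtr <- .applyScaler(x[tr, , drop = FALSE], sc)
      xte <- .applyScaler(x[!tr, , drop = FALSE], sc)
      cvf <- .cvLasso(xtr, y[tr], folds, nLambda)
      p <- as.numeric(predict(cvf$fit, xte, s = cvf$lambda,
                              type = "response"))
      preds[!tr] <- p
      fa[f] <- aurocScore(y[!tr], p)
    }
    foldAuroc[[si]] <- fa
    aurocSeed[si] <- if (pooled) aurocScore(y, preds)
                     else mean(fa, na.rm = TRUE)
    sc <- .fitScaler(x)
    cvAll <- .cvLasso(.applyScaler(x, sc), y, folds, nLambda)
    lambdas[si] <- cvAll$lambda
    cf <- as.numeric(coef(cvAll$fit, s = cvAll$lambda))[-1]
    coefMat[, si] <- cf
  }
  structure(list(
    timepoint = timepoint, seeds = seeds, folds = folds,
    auroc = aurocSeed, fold_auroc = foldAuroc,
    mean_auroc = mean(aurocSeed), sd_auroc = sd(aurocSeed),
    lambda = lambdas, coefficients = coefMat,
    n = length(y)), class = "ModelReport")
}

#' @method print ModelReport
#' @export
print.ModelReport <- function(x, ...) {
  cat("ModelReport:", x$timepoint, "-", length(x$seeds), "seeds,",
      x$folds, "-fold nested stratified CV,", x$n, "samples\n")
  cat(sprintf("  AUROC %.3f +/- %.3f\n", x$mean_auroc, x$sd_auroc))
  invisible(x)
}

#' Consensus top features across model replicates
#'
#' A feature qualifies when (a) it receives a non-zero coefficient in at
#' least \code{minCount} replicates and (b) the absolute value of its
#' across-seed mean weight is at least \code{weightFrac} of the largest such
#' mean weight. Sorted by absolute mean weight, descending.
#'
#' @param report a \code{ModelReport}
#' @param minCount minimum replicates selecting the feature (default 3)
#' @param weightFrac fraction of the largest mean weight (default 0.30)
#' @return data.frame: feature_name, mean_weight, n_selected
#' @export
topFeatures <- function(report, minCount = 3, weightFrac = 0.30) {
  cm <- report$coefficients
  meanW <- rowMeans(cm)
  nSel <- rowSums(cm != 0)
  maxW <- max(abs(meanW))
  keep <- nSel >= minCount & abs(meanW) >= weightFrac * maxW & maxW > 0
  out <- data.frame(feature_name = rownames(cm)[keep],
                    mean_weight = meanW[keep], n_selected = nSel[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$mean_weight)), ]
  rownames(out) <- NULL
  out
}

#' Stratified train/test holdout evaluation
#'
#' Splits patients into stratified train/test parts, selects the penalty by
#' stratified CV within the training set only, standardizes the test set
#' with the training mean and SD, and reports held-out AUROC and AUPRC.
#'
#' @param fm a \linkS4class{FeatureMatrix}
#' @param labels data.frame \code{patient_id}, \code{response}
#' @param timepoint timepoint to model
#' @param trainFrac training fraction (default 0.70)
#' @param seed RNG seed controlling the split
#' @param folds stratified CV folds within training (default 3)
#' @param nLambda penalty-grid size
#' @param trainIdx optional logical vector fixing the split (overrides the
#'   stratified draw); useful for leakage audits
#' @return list: auroc, auprc, n_train, n_test, lambda, coefficients
#' @export
holdoutEval <- function(fm, labels, timepoint, trainFrac = 0.70, seed = 1,
                        folds = 3, nLambda = 50, trainIdx = NULL) {
  td <- .timepointData(fm, labels, timepoint)
  keep <- colSums(!is.na(td$x)) > 0
  x <- td$x[, keep, drop = FALSE]
  y <- td$y
  set.seed(seed)
  if (is.null(trainIdx)) {
    trIdx <- logical(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      nTr <- round(trainFrac * length(idx))
      trIdx[sample(idx, nTr)] <- TRUE
    }
  } else trIdx <- trainIdx
  if (length(unique(y[!trIdx])) < 2)
    stop("evaluation error: test set contains a single class")
  sc <- .fitScaler(x[trIdx, , drop = FALSE])
  xtr <- .applyScaler(x[trIdx, , drop = FALSE], sc)
  xte <- .applyScaler(x[!trIdx, , drop = FALSE], sc)
  cvf <- .cvLasso(xtr, y[trIdx], folds, nLambda)
  p <- as.numeric(predict(cvf$fit, xte, s = cvf$lambda, type = "response"))
  cf <- as.numeric(coef(cvf$fit, s = cvf$lambda))[-1]
  list(timepoint = timepoint, auroc = aurocScore(y[!trIdx], p),
       auprc = auprcScore(y[!trIdx], p),
       n_train = sum(trIdx), n_test = sum(!trIdx), lambda = cvf$lambda,
       coefficients = setNames(cf, colnames(x)))
}
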