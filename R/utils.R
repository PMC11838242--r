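#' Shannon diversity index
#'
#' H = -sum p_i log p_i (natural log) over the positive entries of a count or
#' proportion vector. H is 0 for a single type and log(K) for K equally
#' frequent types.
#'
#' @param x non-negative counts or proportions
#' @return H in nats, or NA if x sums to zero
#' @export
shannonIndex <- function(x) {
  x <- x[x > 0]
  if (!length(x)) return(NA_real_)
  p <- x / sum(x)
  -sum(p * log(p))
}

# gaussian smoothing of a plain matrix; sigma = 0 is the identity
gaussianSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  out <- EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
  matrix(out, nrow(m), ncol(m))
}

# boolean disc of radius r centred in an h x w matrix at (cx, cy), 0-based
discMask <- function(h, w, cx, cy, r) {
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# stratified fold assignment: each class split as evenly as possible
stratifiedFolds <- function(y, k) {
  y <- as.integer(y)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(vapply(split(y, fold), function(v) length(unique(v)), 1L) < 2))
    stop("stratification error: a fold contains a single class")
  fold
}

# AUROC via pROC; returns NA when one class is absent
aurocScore <- function(labels, scores) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

# area under the precision-recall curve (step interpolation over ranked scores)
auprcScore <- function(labels, scores) {
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y == 1)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y == 1)
  sum(prec[y == 1]) / sum(y == 1)  # average precision
}

# pairwise squared distances between rows of a and rows of b (n x 2 each)
crossDist2 <- function(a, b) {
  outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
}
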