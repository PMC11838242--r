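# Channel compensation and detector-drift normalization for mass-based
# multiplexed imaging.
#
# Compensation: contamination (spillover, elemental background, organics,
# slide background) is modelled linearly. A coefficient matrix has one row
# per source channel and one column per target channel; entry (i, j) is the
# fraction of source-i signal appearing in target j. The corrected target is
# target - sum_i coeff[i, j] * smooth(source_i), clipped at zero. Sources are
# gaussian-smoothed so integer counts compensate fractionally.
#
# Drift normalization: detector sensitivity decays over a run. The median
# pulse height (MPH) of each channel is a staining-independent sensitivity
# proxy; a per-channel polynomial is fitted to MPH over acquisition order to
# denoise it, a fixed tuning curve converts MPH to a sensitivity fraction in
# (0, 1], and each image is divided by its sensitivity.

#' Read a compensation matrix from CSV
#'
#' Rows are source channels, columns target channels; the first column holds
#' the source-channel names. Diagonal entries are forced to zero (a channel
#' never compensates itself).
#'
#' @param path CSV path
#' @return numeric matrix with source rownames and target colnames
#' @export
readCompensationMatrix <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  compensationMatrix(m)
}

#' @rdname readCompensationMatrix
#' @param m numeric matrix, source rows x target columns, coefficients >= 0
#' @export
compensationMatrix <- function(m) {
  if (any(m < 0)) stop("compensation coefficients must be >= 0")
  shared <- intersect(rownames(m), colnames(m))
  m[cbind(shared, shared)] <- 0
  m
}

#' Compensate a target channel
#'
#' Subtracts each gaussian-smoothed source channel scaled by its coefficient
#' from the target, then clips negatives to zero. Subtraction is linear, so
#' the result does not depend on source order.
#'
#' @param target numeric matrix, the channel to correct
#' @param sources named list of source-channel matrices (same shape)
#' @param matrix compensation matrix (source rows x target columns)
#' @param targetName column of \code{matrix} to use
#' @param sigma gaussian smoothing sigma (px) applied to sources; default 1
#' @return corrected matrix, same shape as \code{target}
#' @export
compensate <- function(target, sources, matrix, targetName, sigma = 1) {
  for (s in sources)
    if (!identical(dim(s), dim(target)))
      stop("dimension error: source and target shapes differ")
  out <- target
  for (nm in names(sources)) {
    co <- if (nm %in% rownames(matrix) && targetName %in% colnames(matrix))
      matrix[nm, targetName] else 0
    if (co > 0) out <- out - co * gaussianSmooth(sources[[nm]], sigma)
  }
  pmax(out, 0)
}

#' Fit the MPH-to-sensitivity tuning curve
#'
#' Fits a cubic polynomial to a calibration table of (MPH, fraction of
#' maximum signal) pairs measured on a standard sample across detector
#' settings. One curve is used for all images.
#'
#' @param calibration data.frame with columns \code{mph} and \code{fraction}
#'   (fraction of maximum signal, in (0, 1])
#' @param degree polynomial degree (default 3)
#' @return object of class \code{sensitivityCurve}
#' @export
fitSensitivityCurve <- function(calibration, degree = 3) {
  stopifnot(all(c("mph", "fraction") %in% names(calibration)))
  fit <- stats::lm(fraction ~ poly(mph, degree, raw = TRUE), data = calibration)
  structure(list(coef = coef(fit), degree = degree,
                 range = range(calibration$mph)),
            class = "sensitivityCurve")
}

#' Evaluate a sensitivity curve at an MPH value
#'
#' The evaluated sensitivity is clipped to (eps, 1] so normalization never
#' amplifies without bound. MPH values outside the calibrated range are
#' clamped to it.
#'
#' @param curve a \code{sensitivityCurve}
#' @param mph MPH value(s)
#' @param eps sensitivity floor (default 0.05)
#' @export
sensitivityAt <- function(curve, mph, eps = 0.05) {
  mph <- pmin(pmax(mph, curve$range[1]), curve$range[2])
  v <- vapply(mph, function(x)
    sum(curve$coef * x^(0:curve$degree)), numeric(1))
  pmin(pmax(v, eps), 1)
}

#' Fit per-channel MPH drift over a run
#'
#' Per-FOV MPH estimates are noisy; a quadratic polynomial in acquisition
#' order is fitted per channel and the fitted values replace the raw ones.
#'
#' @param mph data.frame with columns \code{fov_index} (acquisition order),
#'   \code{channel}, \code{mph}
#' @param degree polynomial degree (default 2)
#' @return list per channel: fitted values at each observed index, residuals,
#'   and a \code{predict(index)} function
#' @export
fitDrift <- function(mph, degree = 2) {
  stopifnot(all(c("fov_index", "channel", "mph") %in% names(mph)))
  out <- list()
  for (ch in unique(mph$channel)) {
    d <- mph[mph$channel == ch, ]
    if (nrow(d) < 3) stop("fit error: fewer than 3 FOVs for channel ", ch)
    deg <- min(degree, nrow(d) - 1)
    fit <- stats::lm(mph ~ poly(fov_index, deg, raw = TRUE), data = d)
    cf <- coef(fit)
    cf[is.na(cf)] <- 0
    pred <- local({
      cf <- cf; deg <- deg
      function(index) vapply(index, function(x) sum(cf * x^(0:deg)), numeric(1))
    })
    out[[ch]] <- list(fov_index = d$fov_index, fitted = unname(fitted(fit)),
                      residuals = unname(stats::residuals(fit)),
                      predict = pred)
  }
  out
}

#' Normalize an image to 100% sensitivity
#'
#' Divides the image by the sensitivity implied by its (fitted) MPH.
#'
#' @param img channel matrix
#' @param mph fitted MPH value for this image and channel
#' @param curve a \code{sensitivityCurve}
#' @param eps sensitivity floor
#' @export
normalizeImage <- function(img, mph, curve, eps = 0.05) {
  img / sensitivityAt(curve, mph, eps = eps)
}
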