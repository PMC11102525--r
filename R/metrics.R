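#' Bleaching-extent-to-noise ratio (BNR)
#'
#' Bleaching extent is the magnitude of the amplitude reduction over the
#' acquisition; BNR measures it against the image noise in decibels:
#' \deqn{BNR = 20 \log_{10}\frac{\max_t A - \min_t A}{\mathrm{std(noise)}}.}
#'
#' @param series per-voxel amplitude series.
#' @param noise_std noise standard deviation, > 0, estimated over a
#'   signal-free region.
#' @return BNR in dB.
#' @export
bnr <- function(series, noise_std) {
  if (!length(series)) stop("'series' is empty", call. = FALSE)
  if (noise_std <= 0) stop("'noise_std' must be positive", call. = FALSE)
  ext <- max(series) - min(series)
  if (ext == 0) stop("no bleaching detected (max == min)", call. = FALSE)
  20 * log10(ext / noise_std)
}

#' Mean signal power of a region
#'
#' \eqn{P = \sum_{region} v^2 / N}.
#'
#' @param pixels non-empty numeric vector of region values.
#' @return mean squared value.
#' @export
region_power <- function(pixels) {
  if (!length(pixels)) stop("empty region", call. = FALSE)
  mean(pixels^2)
}

#' Power SNR of a segmented image
#'
#' \deqn{SNR = (P_{in} - P_{out}) / P_{out}} with \eqn{P} the mean
#' squared value inside and outside the ROI.  Outside the ROI only noise
#' is assumed; inside, signal plus noise.
#'
#' @param image numeric matrix.
#' @param roi logical mask of the same shape; both the ROI and its
#'   complement must be non-empty.
#' @return SNR (power ratio, not dB).
#' @export
snr <- function(image, roi) {
  if (!identical(dim(image), dim(roi)))
    stop("'roi' shape must match the image", call. = FALSE)
  if (!any(roi) || all(roi))
    stop("ROI and its complement must both be non-empty", call. = FALSE)
  p_out <- region_power(image[!roi])
  if (p_out == 0) stop("outside-ROI power is zero", call. = FALSE)
  (region_power(image[roi]) - p_out) / p_out
}

#' Cosine similarity of two images
#'
#' @param image,reference numeric arrays of identical shape with nonzero
#'   norms.
#' @return \eqn{\langle x, y\rangle / (\|x\|\|y\|)} in \eqn{[-1, 1]}.
#' @export
cosine_similarity <- function(image, reference) {
  if (!identical(dim(image), dim(reference)))
    stop("shapes differ", call. = FALSE)
  x <- as.numeric(image); y <- as.numeric(reference)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm input", call. = FALSE)
  sum(x * y) / (nx * ny)
}

#' ROC curve and AUC of a voxel score map
#'
#' Threshold-sweep ROC of a continuous score map against a binary truth
#' mask, with the AUC computed by the trapezoidal rule; with ties counted
#' half this equals the normalised Mann-Whitney statistic.  Backed by
#' \pkg{pROC}.
#'
#' @param score_map numeric scores (higher = more likely positive).
#' @param truth_mask logical truth labels of the same length/shape; both
#'   classes must be present.
#' @return list with \code{roc} (data.frame of \code{threshold},
#'   \code{fpr}, \code{tpr}) and \code{auc}.
#' @export
roc_auc <- function(score_map, truth_mask) {
  scores <- as.numeric(score_map)
  truth <- as.logical(truth_mask)
  if (length(scores) != length(truth))
    stop("score and truth lengths differ", call. = FALSE)
  if (!any(truth) || all(truth))
    stop("truth mask must contain both classes", call. = FALSE)
  r <- pROC::roc(response = truth, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  list(roc = data.frame(threshold = r$thresholds,
                        fpr = 1 - r$specificities,
                        tpr = r$sensitivities),
       auc = as.numeric(r$auc))
}

#' Sensitivity gain of temporal unmixing over background thresholding
#'
#' Conventional detection must threshold above the brightest unbleachable
#' background voxel (the "background roof"); temporal unmixing only needs
#' to clear the noise floor of the tag-amplitude map.  The gain is the
#' ratio of the two thresholds.
#'
#' @param background_roof background-roof threshold, > 0.
#' @param pattern_noise_floor tag-map noise-floor threshold, > 0.
#' @return gain ratio.
#' @export
sensitivity_gain <- function(background_roof, pattern_noise_floor) {
  if (background_roof <= 0 || pattern_noise_floor <= 0)
    stop("thresholds must be positive", call. = FALSE)
  background_roof / pattern_noise_floor
}
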