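#' Mask-overlap preprocessing configuration
#'
#' Parameters of the contrast-boosting chain applied before the baseline
#' detector: 3x3 median filter, gamma correction, white top-hat segmentation
#' of bright calcification-like foci, and additive superimposition of the
#' binary mask on the original image.
#'
#' @param gamma_exponent Positive gamma for contrast correction; the default
#'   2 darkens mid-tones, relatively boosting the bright calcifications.
#' @param tophat_radius Disc structuring-element radius in pixels (>= 1).
#' @param mask_threshold_mode \code{"otsu"} (adaptive) or \code{"fixed"}.
#' @param fixed_threshold Threshold on the top-hat response when
#'   \code{mask_threshold_mode = "fixed"}.
#' @param overlay_gain Non-negative gain multiplying the mask (in units of
#'   full intensity scale) added to the original image.
#' @return A list of class \code{preprocess_config}.
#' @export
preprocess_config <- function(gamma_exponent = 2,
                              tophat_radius = 3L,
                              mask_threshold_mode = c("otsu", "fixed"),
                              fixed_threshold = 0.1,
                              overlay_gain = 0.5) {
  mask_threshold_mode <- match.arg(mask_threshold_mode)
  if (gamma_exponent <= 0) stopf("gamma_exponent must be > 0")
  if (tophat_radius < 1) stopf("tophat_radius must be >= 1")
  if (overlay_gain < 0) stopf("overlay_gain must be >= 0")
  structure(list(
    gamma_exponent = gamma_exponent, tophat_radius = as.integer(tophat_radius),
    mask_threshold_mode = mask_threshold_mode,
    fixed_threshold = fixed_threshold, overlay_gain = overlay_gain
  ), class = "preprocess_config")
}

check_image2d <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) stopf("input must be a 2-D numeric matrix")
  invisible(image)
}

#' 3x3 median filter
#'
#' Each output pixel is the median of its 3x3 neighbourhood; borders use edge
#' replication.
#'
#' @param image 2-D numeric matrix.
#' @return Filtered matrix of the same shape.
#' @export
median3 <- function(image) {
  check_image2d(image)
  cpp_median3(image)
}

#' Gamma correction
#'
#' Normalizes intensities to \code{[0, 1]} over the image's own range, raises
#' them to \code{gamma_exponent}, and rescales back to the original range.
#' Monotone and range-preserving; a constant image is returned unchanged.
#'
#' @param image 2-D numeric matrix.
#' @param gamma_exponent Positive exponent.
#' @return Corrected matrix.
#' @export
gamma_correct <- function(image, gamma_exponent) {
  check_image2d(image)
  if (!is.finite(gamma_exponent) || gamma_exponent <= 0) {
    stopf("gamma_exponent must be > 0")
  }
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)
  ((image - lo) / (hi - lo))^gamma_exponent * (hi - lo) + lo
}

# Disc structuring element as (row, col) integer offsets.
disc_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= r^2 + 1e-9
  as.matrix(g[keep, c("dr", "dc")])
}

# Grayscale opening (erosion then dilation) with a disc SE, edge replication.
gray_opening <- function(image, radius) {
  off <- disc_offsets(radius)
  storage.mode(off) <- "integer"
  cpp_morph(cpp_morph(image, off, FALSE), off, TRUE)
}

#' White top-hat calcification mask
#'
#' Computes the white top-hat response (image minus its morphological opening
#' with a disc of \code{tophat_radius}) and thresholds it to a binary mask of
#' bright, small-scale structures. Thresholding is Otsu on the response by
#' default, or a fixed response threshold.
#'
#' @param image 2-D numeric matrix.
#' @param config A [preprocess_config()].
#' @return Binary (0/1) matrix of the same shape.
#' @export
tophat_mask <- function(image, config = preprocess_config()) {
  check_image2d(image)
  if (config$tophat_radius < 1) stopf("tophat_radius must be >= 1")
  th <- image - gray_opening(image, config$tophat_radius)
  mx <- max(th)
  if (mx <= 0) return(matrix(0, nrow(image), ncol(image)))
  if (config$mask_threshold_mode == "fixed") {
    thr <- config$fixed_threshold
  } else {
    thr <- EBImage::otsu(EBImage::Image(th / mx), range = c(0, 1)) * mx
  }
  (th > thr) + 0
}

#' Mask-overlap preprocessing
#'
#' The full chain: 3x3 median filter, gamma correction, top-hat segmentation,
#' then superimposition of the binary mask onto the original image:
#' \code{clip(original + overlay_gain * mask)} on the \code{[0, 1]} intensity
#' scale. Mask-positive pixels become strictly brighter unless already
#' saturated.
#'
#' @param image 2-D numeric matrix in \code{[0, 1]}.
#' @param config A [preprocess_config()].
#' @return Preprocessed matrix, same shape, clipped to \code{[0, 1]}.
#' @export
mask_overlap <- function(image, config = preprocess_config()) {
  check_image2d(image)
  filtered <- median3(image)
  corrected <- gamma_correct(filtered, config$gamma_exponent)
  mask <- tophat_mask(corrected, config)
  pmin(pmax(image + config$overlay_gain * mask, 0), 1)
}
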